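## Model checkpointing: a JSON config sidecar plus (for the transformer) a
## single serialized weights file.

#' Save / load selection models
#'
#' `save_selection_model` writes `<stem>.json` describing the model; the
#' transformer's weights go to `<stem>.rds`. Baselines and analytic
#' ground-truth models are fully captured by the JSON file.
#'
#' @param model a selection model.
#' @param stem checkpoint path without extension.
#' @return `stem`, invisibly (`save`); the model (`load`).
#' @export
save_selection_model <- function(model, stem) {
  if (inherits(model, "single_factor_model")) {
    cfg <- list(type = "single_factor", beta = model$beta,
                theta = model$params$theta)
  } else if (inherits(model, "per_position_model")) {
    cfg <- list(type = "per_position", beta = model$beta,
                max_len = model$max_len, theta = model$params$theta)
  } else if (inherits(model, "ground_truth_model")) {
    cfg <- list(type = "ground_truth", spec = unclass(model$spec))
  } else if (inherits(model, "transformer_model")) {
    cfg <- list(type = "transformer", config = unclass(model$config))
    saveRDS(model$params, paste0(stem, ".rds"), version = 2)
  } else {
    stop("unsupported model type")
  }
  jsonlite::write_json(cfg, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(stem)
}

#' @rdname save_selection_model
#' @export
load_selection_model <- function(stem) {
  json_path <- if (grepl("\\.json$", stem)) stem else paste0(stem, ".json")
  stem <- sub("\\.json$", "", json_path)
  cfg <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  switch(cfg$type,
         single_factor = {
           m <- single_factor_model(beta = cfg$beta)
           m$params$theta <- cfg$theta
           m
         },
         per_position = {
           m <- per_position_model(max_len = cfg$max_len, beta = cfg$beta)
           m$params$theta <- cfg$theta
           m
         },
         ground_truth = {
           sp <- do.call(selection_spec, cfg$spec[c("family", "value",
                                                    "baseline", "amplitude",
                                                    "period",
                                                    "hydrophobic_penalty",
                                                    "bounds")])
           gen_ground_truth(sp)
         },
         transformer = {
           cc <- cfg$config
           config <- selection_model_config(family = "transformer",
                                            heads = cc$heads,
                                            d_head = cc$d_head,
                                            layers = cc$layers,
                                            ff_mult = cc$ff_mult,
                                            dropout = cc$dropout,
                                            max_len = cc$max_len,
                                            beta = cc$beta)
           m <- .build_transformer(config, seed = 1L)
           m$params <- readRDS(paste0(stem, ".rds"))
           m
         },
         stop("unknown checkpoint type: ", cfg$type))
}
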