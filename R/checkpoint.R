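#' Save a model checkpoint
#'
#' Serializes the configuration and every named parameter array to a
#' single JSON file (schema-versioned, full numeric precision). Text-based
#' so checkpoints are portable and diffable.
#'
#' @param params An `aten_params`.
#' @param cfg The matching `aten_config`.
#' @param path Output path (`.json`).
#' @param extra Optional named list stored verbatim (e.g. feature
#'   configuration, training seed).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(params, cfg, path, extra = list()) {
  enc <- function(x) {
    if (is.array(x) || is.matrix(x)) list(dim = dim(x), data = as.vector(x))
    else list(dim = length(x), data = as.vector(x))
  }
  flat <- list(
    schema = "atenet-checkpoint-1",
    config = unclass(cfg),
    extra = extra,
    arrays = list(
      W_in = enc(params$W_in), b_in = enc(params$b_in),
      fc_W = enc(params$fc_W), fc_b = enc(params$fc_b),
      hier_q = enc(params$hier_q), hier_Wk = enc(params$hier_Wk),
      Wo = enc(params$Wo), bo = enc(params$bo)
    ),
    layers = lapply(params$layers, function(lp) lapply(lp, enc)),
    branches = lapply(params$branches, function(br) lapply(br, enc))
  )
  jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Path written by [save_checkpoint()].
#' @return List with `params` (`aten_params`), `cfg` (`aten_config`) and
#'   `extra`.
#' @export
load_checkpoint <- function(path) {
  flat <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(flat$schema) || !identical(flat$schema, "atenet-checkpoint-1"))
    stop("format error: unrecognized checkpoint schema")
  dec <- function(e) {
    d <- as.integer(unlist(e$dim))
    x <- as.numeric(unlist(e$data))
    if (length(d) > 1) array(x, d) else x
  }
  cfgl <- lapply(flat$config, unlist)
  cfg <- aten_config(d_input = cfgl$d_input, d_model = cfgl$d_model,
                     n_layers = cfgl$n_layers,
                     kernel_sizes = unlist(cfgl$kernel_sizes),
                     d_int = cfgl$d_int, n_classes = cfgl$n_classes,
                     dropout_p = cfgl$dropout_p,
                     use_positional = cfgl$use_positional,
                     d_hier = cfgl$d_hier, attn_scale = cfgl$attn_scale,
                     use_attention = cfgl$use_attention,
                     use_conv = cfgl$use_conv,
                     use_multiscale = cfgl$use_multiscale)
  a <- flat$arrays
  params <- structure(list(
    W_in = dec(a$W_in), b_in = dec(a$b_in),
    layers = lapply(seq_len(cfg$n_layers), function(l)
      lapply(flat$layers[[l]], dec)),
    branches = lapply(seq_along(flat$branches), function(m)
      lapply(flat$branches[[m]], dec)),
    fc_W = dec(a$fc_W), fc_b = dec(a$fc_b),
    hier_q = dec(a$hier_q), hier_Wk = dec(a$hier_Wk),
    Wo = dec(a$Wo), bo = dec(a$bo)
  ), class = "aten_params")
  list(params = params, cfg = cfg, extra = lapply(flat$extra, unlist))
}
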