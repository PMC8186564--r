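# Plain-text serialization of fitted hazard-GP models: named groups
# (filters, warp, kernels, variational state, inducing inputs, config)
# written as delimited matrices plus a JSON header.

#' Write / read a fitted hazard-GP model as plain text
#'
#' The model state is stored as a directory of TSV matrices (filters,
#' inducing inputs, variational covariance factor) and a JSON file with
#' scalars and vectors (warp, kernel hyperparameters, ARD moments,
#' configuration), so fitted models survive text-only storage.
#'
#' @param model a fitted `vc_gp_model`.
#' @param dir output directory.
#' @return `write_gp_model` returns `dir` invisibly; `read_gp_model` the
#'   restored `vc_gp_model`.
#' @export
write_gp_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wm <- function(x, f) utils::write.table(x, file.path(dir, f), sep = "\t",
                                          row.names = FALSE,
                                          col.names = FALSE)
  wm(model$par$W_mean, "filters_mean.tsv")
  wm(model$par$W_logsd, "filters_logsd.tsv")
  wm(model$par$L_raw, "variational_L_raw.tsv")
  wm(model$Z_S, "inducing_stimulus.tsv")
  head <- list(
    m0 = model$par$m0, mu_u = model$par$mu_u,
    log_s2s = model$par$log_s2s, log_s2t = model$par$log_s2t,
    log_lt = model$par$log_lt,
    warp_a_raw = model$par$warp_a_raw, warp_b_raw = model$par$warp_b_raw,
    warp_c = model$par$warp_c,
    Z_t = model$Z_t, Z_block = model$Z_block, blocks = model$blocks,
    Enu = model$Enu, Elognu = model$Elognu, kl_nu = model$kl_nu,
    cfg = model$cfg[setdiff(names(model$cfg), "profile")],
    task_cfg = local({
      tc <- model$task_cfg[!vapply(model$task_cfg, is.function, NA)]
      tc$block_offsets <- as.list(tc$block_offsets) # keep names in JSON
      tc
    })
  )
  writeLines(jsonlite::toJSON(head, auto_unbox = TRUE, digits = NA),
             file.path(dir, "model.json"))
  invisible(dir)
}

#' @rdname write_gp_model
#' @export
read_gp_model <- function(dir) {
  rm_ <- function(f) as.matrix(utils::read.table(file.path(dir, f),
                                                 sep = "\t"))
  head <- jsonlite::fromJSON(file.path(dir, "model.json"))
  cfg <- do.call(gp_config, head$cfg[names(head$cfg) %in%
                                       names(formals(gp_config))])
  tc <- lapply(head$task_cfg, unlist) # JSON objects back to named vectors
  task_cfg <- do.call(task_config,
                      tc[names(tc) %in% names(formals(task_config))])
  par <- list(
    m0 = head$m0, mu_u = head$mu_u,
    L_raw = unname(rm_("variational_L_raw.tsv")),
    log_s2s = head$log_s2s, log_s2t = head$log_s2t, log_lt = head$log_lt,
    warp_a_raw = head$warp_a_raw, warp_b_raw = head$warp_b_raw,
    warp_c = head$warp_c,
    W_mean = unname(rm_("filters_mean.tsv")),
    W_logsd = unname(rm_("filters_logsd.tsv"))
  )
  st <- list(blocks = as.character(unlist(head$blocks)), Enu = head$Enu,
             Elognu = head$Elognu, kl_nu = head$kl_nu,
             Z_S = unname(rm_("inducing_stimulus.tsv")),
             Z_t = head$Z_t,
             Z_block = as.character(unlist(head$Z_block)),
             gh = pracma::gaussHermite(cfg$gh_points))
  model <- finalize_gp_model(par, c(st, list(cfg = cfg)), cfg, task_cfg,
                             numeric(0), numeric(0))
  model
}
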