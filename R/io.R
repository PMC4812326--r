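TRACE_SCHEMA_VERSION <- "1.0"
TRACE_HEADER <- c("time_s", "stage_um", "cantilever_um")
SIM_HEADER <- c("time_s", "stage_um", "cantilever_um", "e_um", "force_nN",
                "delta_um", "tension_nN", "tmaxwell_nN")

sidecar_path <- function(path) {
  paste0(sub("\\.csv$", "", path, ignore.case = TRUE), ".json")
}

params_to_list <- function(p) list(T0 = p$T0, k1 = p$k1, k2 = p$k2, eta = p$eta)

#' Write an experiment trace to CSV plus JSON sidecar
#'
#' The CSV holds exactly the measured channels (`time_s, stage_um,
#' cantilever_um`, full-precision floats); everything else (half-length,
#' cantilever constant, condition, seed, ground truth for synthetic
#' traces, schema version) goes to a JSON sidecar next to it.
#'
#' @param trace An [experiment_trace()].
#' @param path Output CSV path; the sidecar replaces `.csv` with `.json`.
#' @return Invisibly, the two paths written.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "experiment_trace"))
  df <- data.frame(time_s = trace$t, stage_um = trace$delta_s,
                   cantilever_um = trace$delta_clv)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  truth <- attr(trace, "truth")
  meta <- list(schema_version = TRACE_SCHEMA_VERSION,
               d_um = attr(trace, "geometry")$d,
               k_clv_nN_per_um = attr(trace, "probe")$k_clv,
               condition = attr(trace, "condition"),
               seed = attr(trace, "seed"),
               package_version = as.character(packageVersion("fiberSLS")))
  if (!is.null(truth)) {
    meta$truth <- list(params = params_to_list(truth$params))
  }
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(c(csv = path, sidecar = sidecar_path(path)))
}

#' Read an experiment trace from CSV plus JSON sidecar
#'
#' Validates the CSV header (exactly `time_s,stage_um,cantilever_um`) and
#' the sidecar's required fields (`d_um`, `k_clv_nN_per_um`).
#'
#' @param path Trace CSV path (sidecar expected next to it).
#' @return An [experiment_trace()].
#' @examples
#' path <- system.file("extdata", "synthetic_trace.csv", package = "fiberSLS")
#' tr <- read_trace(path)
#' head(tr)
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop("metadata sidecar not found: ", sp)
  df <- read.csv(path, check.names = FALSE)
  if (!identical(names(df), TRACE_HEADER)) {
    bad <- setdiff(names(df), TRACE_HEADER)
    stop(sprintf("trace CSV header must be exactly '%s'; offending column(s): %s",
                 paste(TRACE_HEADER, collapse = ","),
                 if (length(bad)) paste(bad, collapse = ", ") else "missing columns"))
  }
  if (nrow(df) < 2) stop("trace CSV has fewer than 2 samples")
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  for (f in c("d_um", "k_clv_nN_per_um")) {
    if (is.null(meta[[f]])) stop("sidecar is missing required field: ", f)
  }
  if (meta$d_um <= 0) stop("sidecar validation: d_um must be > 0")
  if (meta$k_clv_nN_per_um <= 0) stop("sidecar validation: k_clv_nN_per_um must be > 0")
  truth <- NULL
  if (!is.null(meta$truth)) {
    tp <- meta$truth$params
    truth <- list(params = mechanical_params(tp$T0, tp$k1, tp$k2, tp$eta))
  }
  experiment_trace(df$time_s, df$stage_um, df$cantilever_um,
                   d = meta$d_um, k_clv = meta$k_clv_nN_per_um,
                   condition = if (is.null(meta$condition)) "CTRL" else meta$condition,
                   seed = if (is.null(meta$seed)) NA_integer_ else meta$seed,
                   truth = truth)
}

#' Write a simulated trace to CSV plus JSON sidecar
#'
#' @param sim A `sim_trace` from [forward_simulate()].
#' @param path Output CSV path.
#' @return Invisibly, the paths written.
#' @export
write_sim_trace <- function(sim, path) {
  stopifnot(inherits(sim, "sim_trace"))
  df <- setNames(sim[, c("t", "delta_s", "delta_clv", "e", "F_clv",
                         "delta", "T", "T_m")], SIM_HEADER)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  proto <- attr(sim, "protocol")
  solver <- attr(sim, "solver")
  meta <- list(schema_version = TRACE_SCHEMA_VERSION,
               d_um = attr(sim, "geometry")$d,
               k_clv_nN_per_um = attr(sim, "probe")$k_clv,
               params = params_to_list(attr(sim, "params")),
               protocol = proto[c("v0", "delta_s_star", "t_hold", "sample_rate")],
               solver = solver[c("rtol", "atol", "method")],
               package_version = as.character(packageVersion("fiberSLS")))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(csv = path, sidecar = sidecar_path(path)))
}

#' Serialize a fit result to JSON
#'
#' Writes the recovered parameters (with units), the staged estimates
#' (intercept, relaxation), the aggregated misfit, grid diagnostics, the
#' configuration used and the package version, for provenance.
#'
#' @param fit A `fit_result`.
#' @param path Output JSON path.
#' @param config The [fit_config()] used (embedded for provenance).
#' @return Invisibly, `path`.
#' @export
write_fit_result <- function(fit, path, config = NULL) {
  stopifnot(inherits(fit, "fit_result"))
  cfg <- if (is.null(config)) NULL else
    config[c("coarse_step", "fine_step", "k1_bounds", "k2_bounds", "e_min")]
  out <- list(
    schema_version = TRACE_SCHEMA_VERSION,
    params = c(params_to_list(fit$params),
               units = list(list(T0 = "nN", k1 = "nN/um", k2 = "nN/um",
                                 eta = "nN.s/um"))),
    T0_intercept_nN = as.numeric(fit$T0_hat),
    loading_slope_nN_per_um = attr(fit$T0_hat, "slope"),
    relaxation = fit$relaxation[c("tau", "e_inf", "r_squared", "t_star",
                                  "e_star", "flagged", "degenerate")],
    error = as.numeric(fit$error),
    diagnostics = list(n_eval = fit$diagnostics$n_eval,
                       runner_up_gap = fit$diagnostics$runner_up_gap,
                       boundary = fit$diagnostics$boundary,
                       tie = fit$diagnostics$tie,
                       degenerate_maxwell = fit$diagnostics$degenerate_maxwell),
    config = cfg,
    package_version = as.character(packageVersion("fiberSLS")))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}
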