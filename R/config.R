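#' Classification-cascade configuration
#'
#' Collects every threshold of the three-stage cascade, with the study's
#' printed cut-offs as defaults: expression at TPM >= 1; Src effect at
#' >= 3-fold with p < 0.05; contact reversal at >= 40% inverse change with
#' p < 0.08 (the stated value for that stage); cadherin dependence at
#' >= 2-fold with p < 0.05. All fold/percent boundaries are inclusive
#' ("at least" wording); p boundaries are strict.
#'
#' @param min_tpm Inclusive expression threshold in TPM.
#' @param src_fold Minimum Src fold change (>= 1).
#' @param src_alpha Src-stage p cut-off (strict).
#' @param reversal_fraction Minimum inverse relative change in (0, 1).
#' @param reversal_alpha Reversal-stage p cut-off.
#' @param cdh_fold Minimum cadherin differential fold (>= 1).
#' @param cdh_alpha Cadherin-stage p cut-off.
#' @param pseudocount Additive stabilizer for fold changes (TPM units).
#' @param filter_scope `"group_mean"`: a gene counts as expressed when some
#'   group's mean TPM reaches `min_tpm`; `"any_sample"`: any single sample
#'   suffices.
#' @param reversal_mode `"inverse_change"` (default): reversal is a change of
#'   at least `reversal_fraction` of the transformed-self level, opposite in
#'   sign to the Src effect. `"restoration"`: reversal is a move of at least
#'   `reversal_fraction` of the way from the transformed-self level back
#'   toward the normal-self baseline.
#' @param log_transform If `TRUE`, t-tests run on `log2(TPM + 1)` replicate
#'   values (fold changes stay on the raw scale).
#' @param p_adjust `"none"` (default, raw cut-offs) or `"BH"` for
#'   Benjamini-Hochberg adjustment within each stage.
#' @return A `cascade_config` list.
#' @export
#' @examples
#' cascade_config()
#' cascade_config(src_fold = 4, reversal_alpha = 0.05)
cascade_config <- function(min_tpm = 1,
                           src_fold = 3, src_alpha = 0.05,
                           reversal_fraction = 0.40, reversal_alpha = 0.08,
                           cdh_fold = 2, cdh_alpha = 0.05,
                           pseudocount = 1,
                           filter_scope = c("group_mean", "any_sample"),
                           reversal_mode = c("inverse_change", "restoration"),
                           log_transform = FALSE,
                           p_adjust = c("none", "BH")) {
  cfg <- list(
    min_tpm = min_tpm,
    src_fold = src_fold, src_alpha = src_alpha,
    reversal_fraction = reversal_fraction, reversal_alpha = reversal_alpha,
    cdh_fold = cdh_fold, cdh_alpha = cdh_alpha,
    pseudocount = pseudocount,
    filter_scope = match.arg(filter_scope),
    reversal_mode = match.arg(reversal_mode),
    log_transform = isTRUE(log_transform),
    p_adjust = match.arg(p_adjust)
  )
  stopifnot_config(cfg)
  structure(cfg, class = "cascade_config")
}

stopifnot_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  chk(is.numeric(cfg$min_tpm) && cfg$min_tpm >= 0, "min_tpm must be >= 0")
  chk(cfg$src_fold >= 1, "src_fold must be >= 1")
  chk(cfg$cdh_fold >= 1, "cdh_fold must be >= 1")
  for (a in c("src_alpha", "reversal_alpha", "cdh_alpha")) {
    # 0 is allowed as a degenerate "select nothing" cut-off
    chk(cfg[[a]] >= 0 && cfg[[a]] <= 1, sprintf("%s must be in [0, 1]", a))
  }
  chk(cfg$reversal_fraction > 0 && cfg$reversal_fraction < 1,
      "reversal_fraction must be in (0, 1)")
  chk(cfg$pseudocount >= 0, "pseudocount must be >= 0")
  invisible(cfg)
}

#' @export
print.cascade_config <- function(x, ...) {
  cat("<cascade_config>\n")
  cat(sprintf("  expression:  TPM >= %g (%s)\n", x$min_tpm, x$filter_scope))
  cat(sprintf("  Src effect:  fold >= %g, p < %g\n", x$src_fold, x$src_alpha))
  cat(sprintf("  reversal:    |change| >= %g (%s), p < %g\n",
              x$reversal_fraction, x$reversal_mode, x$reversal_alpha))
  cat(sprintf("  cadherin:    fold >= %g, p < %g\n", x$cdh_fold, x$cdh_alpha))
  cat(sprintf("  pseudocount: %g; log t-tests: %s; p adjust: %s\n",
              x$pseudocount, x$log_transform, x$p_adjust))
  invisible(x)
}

# Apply user overrides (named list) to a cascade_config; unknown keys error.
apply_config_overrides <- function(cfg, overrides) {
  if (length(overrides) == 0) return(cfg)
  unknown <- setdiff(names(overrides), names(unclass(cfg)))
  if (length(unknown) > 0) {
    stop(sprintf("unknown cascade config key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  do.call(cascade_config, modifyList(unclass(cfg), overrides))
}
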