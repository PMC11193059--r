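#' Published CASF-2016 core-set leaderboard
#'
#' Literature-reported performance of this model family (v1: protein +
#' pocket + ligand; v2: protein + ligand only) and of four established
#' structure- or sequence-based affinity predictors on the CASF-2016 core
#' test set. These printed values are inputs to the reporting helpers; the
#' package does not recompute them (doing so would require the full PDBbind
#' download and days of training).
#'
#' @return A data frame with columns `method`, `rmse`, `mae`, `sd`, `ci`,
#'   `r`; the first two rows are the v1 and v2 variants of this package's
#'   model.
#' @export
casf2016_leaderboard <- function() {
  data.frame(
    method = c("v1", "v2", "GraphscoreDTA", "DeepDTAF", "DLSSAffinity",
               "Pafnucy"),
    rmse = c(1.224, 1.266, 1.349, 1.356, 1.401, 1.423),
    mae  = c(1.003, 1.014, 1.053, 1.075, 1.134, 1.135),
    sd   = c(1.166, 1.222, 1.281, 1.337, 1.336, 1.378),
    ci   = c(0.820, 0.812, 0.810, 0.798, 0.794, 0.787),
    r    = c(0.845, 0.827, 0.810, 0.789, 0.789, 0.774),
    stringsAsFactors = FALSE
  )
}

#' Relative improvement between two metric values
#'
#' For error-like metrics (RMSE, MAE, SD; smaller is better) the
#' improvement of `new` over `ref` is `(ref - new) / ref`. For score-like
#' metrics (CI, R; larger is better) it is `(new - ref) / ref`. Returned in
#' percent.
#'
#' @param new metric value of the method under evaluation.
#' @param ref metric value of the reference method.
#' @param direction `"lower"` if smaller values are better, `"higher"`
#'   otherwise.
#' @return Improvement in percent (positive = `new` is better).
#' @export
relative_improvement <- function(new, ref, direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(new), is.numeric(ref), all(ref != 0))
  if (direction == "lower") 100 * (ref - new) / ref else 100 * (new - ref) / ref
}

#' Leaderboard comparison summary
#'
#' Recomputes, from a leaderboard table of printed metric values, the
#' derived comparison figures typically quoted alongside it: the relative
#' improvement of the top method over each competitor for every metric, the
#' relative performance loss of the pocket-free v2 variant versus v1, and
#' the absolute CI gap between the top method and the best competitor.
#'
#' @param board a data frame as returned by [casf2016_leaderboard()].
#' @return A list with `improvements` (data frame: method x metric,
#'   percent improvement of the first row's method over that method),
#'   `v2_loss` (named vector of percent losses of row "v2" vs row "v1"),
#'   and `ci_gap` (absolute CI difference between the top method and the
#'   best of the remaining methods).
#' @examples
#' s <- leaderboard_summary(casf2016_leaderboard())
#' round(s$improvements["GraphscoreDTA", "rmse"], 2)  # 9.27
#' @export
leaderboard_summary <- function(board = casf2016_leaderboard()) {
  stopifnot(all(c("method", "rmse", "mae", "sd", "ci", "r") %in% names(board)),
            nrow(board) >= 2L)
  lower <- c("rmse", "mae", "sd")
  higher <- c("ci", "r")
  top <- board[1L, ]
  rest <- board[-1L, ]
  metric_names <- c(lower, higher)
  imp <- as.data.frame(lapply(stats::setNames(metric_names, metric_names),
                              function(mname) {
    dirn <- if (mname %in% lower) "lower" else "higher"
    relative_improvement(top[[mname]], rest[[mname]], direction = dirn)
  }), row.names = rest$method)

  v2_loss <- NULL
  if (all(c("v1", "v2") %in% board$method)) {
    v1 <- board[board$method == "v1", ]
    v2 <- board[board$method == "v2", ]
    v2_loss <- vapply(c(lower, higher), function(mname) {
      dirn <- if (mname %in% lower) "lower" else "higher"
      -relative_improvement(v2[[mname]], v1[[mname]], direction = dirn)
    }, numeric(1))
  }

  others <- rest[!rest$method %in% c("v1", "v2"), ]
  ci_gap <- if (nrow(others)) top$ci - max(others$ci) else NA_real_
  list(improvements = imp, v2_loss = v2_loss, ci_gap = ci_gap)
}
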