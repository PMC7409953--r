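#' Root-mean-square deviation
#'
#' sqrt(sum((calc - exp)^2) / M) between back-calculated and experimental
#' values; for M = 1 this is the absolute deviation, the convention used for
#' single-restraint types (mean FRET efficiency, hydrodynamic radius).
#'
#' @param calc,exp Numeric vectors of equal length M >= 1.
#' @return Non-negative deviation.
#' @export
rmsd <- function(calc, exp) {
  if (length(calc) != length(exp)) stop("length mismatch")
  if (length(calc) == 0L) return(NA_real_)
  sqrt(sum((calc - exp)^2) / length(calc))
}

#' Ensemble composition by population label
#'
#' Multiset-counted fractions of each population label among the members of
#' one or more ensemble states, averaged over states. Used to track how
#' optimization shifts the balance between parent sub-populations of a
#' mixed pool.
#'
#' @param states A single member-index vector / \code{ensemble_state}, or a
#'   list of them.
#' @param labels Character vector of per-conformer population labels for the
#'   whole pool.
#' @return Named numeric vector of fractions summing to 1.
#' @export
pool_composition <- function(states, labels) {
  if (anyNA(labels)) stop("every pool conformer must be labeled")
  labels <- as.character(labels)
  if (inherits(states, "ensemble_state") || is.numeric(states))
    states <- list(states)
  lev <- sort(unique(labels))
  fr <- vapply(states, function(s) {
    m <- .members_of(s)
    if (min(m) < 1L || max(m) > length(labels))
      stop("member index outside the labeled pool")
    tab <- table(factor(labels[m], levels = lev))
    as.numeric(tab) / length(m)
  }, numeric(length(lev)))
  out <- if (is.matrix(fr)) rowMeans(fr) else fr
  names(out) <- lev
  out
}

#' Replicate mean and sample standard deviation
#'
#' @param values Numeric vector over replicates (>= 1 value).
#' @return List \code{(mean, sd, n)}; \code{sd} is the sample (N-1)
#'   standard deviation, NA for a single value.
#' @export
aggregate_mean_sd <- function(values) {
  if (length(values) < 1L) stop("need at least one value")
  list(mean = mean(values),
       sd = if (length(values) > 1L) stats::sd(values) else NA_real_,
       n = length(values))
}

#' Histogram of radius-of-gyration values
#'
#' Fixed 0.5 Angstrom binning so distributions are comparable across runs.
#'
#' @param rg Numeric vector of R_g values (Angstrom).
#' @param binwidth Bin width (default 0.5 Angstrom).
#' @return Data frame with bin midpoints and counts.
#' @export
rg_histogram <- function(rg, binwidth = 0.5) {
  lo <- floor(min(rg) / binwidth) * binwidth
  hi <- ceiling(max(rg) / binwidth) * binwidth
  if (hi <= lo) hi <- lo + binwidth
  breaks <- seq(lo, hi, by = binwidth)
  h <- hist(rg, breaks = breaks, plot = FALSE)
  data.frame(mid = h$mids, count = h$counts)
}

#' Build a score report
#'
#' Collects a replicate run into a serializable report: per-type score and
#' deviation mean (sd), optimized and unoptimized, plus pool composition and
#' an optional R_g summary — the per-type "Score | RMSD" layout.
#'
#' @param run A \code{replicate_run}.
#' @param rg Optional per-conformer R_g values for the pool; the report then
#'   includes the mean/sd and 0.5-A histogram over the optimized members.
#' @return A list of class \code{"score_report"}.
#' @export
score_report <- function(run, rg = NULL) {
  stopifnot(inherits(run, "replicate_run"))
  rep_tab <- data.frame(
    datatype = run$summary$type_totals$datatype,
    score_mean = run$summary$type_totals$mean,
    score_sd = run$summary$type_totals$sd,
    rmsd_mean = run$summary$rmsd$mean,
    rmsd_sd = run$summary$rmsd$sd,
    unopt_score_mean = run$summary$initial_type_totals$mean,
    unopt_score_sd = run$summary$initial_type_totals$sd,
    unopt_rmsd_mean = run$summary$initial_rmsd$mean,
    unopt_rmsd_sd = run$summary$initial_rmsd$sd)
  out <- list(active = run$active,
              mode = run$opt$mode,
              n_replicates = length(run$replicates),
              n_steps = run$opt$n_steps,
              ensemble_size = run$opt$ensemble_size,
              table = rep_tab,
              composition = if (!is.null(run$composition))
                as.list(run$composition),
              rng = run$rng)
  if (!is.null(rg)) {
    members <- unlist(lapply(run$replicates, `[[`, "members"))
    vals <- rg[members]
    out$rg <- c(aggregate_mean_sd(vals), list(histogram = rg_histogram(vals)))
  }
  class(out) <- "score_report"
  out
}

#' Write a report as JSON
#'
#' Serialization is lossless for round-tripping (full numeric precision).
#'
#' @param report A \code{score_report} (or any list).
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("score_report: %s optimization of %s, %d replicates x %d steps, N = %d\n",
              x$mode, paste(x$active, collapse = "+"), x$n_replicates,
              x$n_steps, x$ensemble_size))
  tab <- x$table
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-5s score %8.2f (%.2f)   rmsd %8.4f (%.4f)\n",
                tab$datatype[i], tab$score_mean[i], tab$score_sd[i],
                tab$rmsd_mean[i], tab$rmsd_sd[i]))
  if (!is.null(x$composition)) {
    cat("  composition:",
        paste(sprintf("%s = %.3f", names(x$composition),
                      unlist(x$composition)), collapse = ", "), "\n")
  }
  invisible(x)
}
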