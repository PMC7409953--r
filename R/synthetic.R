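#' Define a synthetic ground truth
#'
#' Describes a conformer pool partitioned into labelled sub-populations with
#' distinct observable distributions, from which observable tables and
#' pseudo-experimental restraints can be realized. The construction mirrors
#' a mixed pool assembled from parent ensembles with different local
#' structure (backbone phi preferences, chemical-shift offsets) and global
#' compaction (contact distances, R_g, R_h, dye-to-dye distances), so that
#' every scoring and optimization path is testable without external
#' predictors.
#'
#' Per-conformer observables stay physically coherent with the
#' back-calculation chain: phi angles are drawn wrapped-normal and converted
#' through the Karplus cosine terms (so cos2 = cos^2 per conformer),
#' distances are drawn log-normal (positivity), and FRET efficiencies are
#' induced from distances via the polymer-scaled Foerster relation, never
#' drawn directly.
#'
#' @param n_pool Pool size (default 1000).
#' @param populations List of population descriptors; each a list with
#'   fields \code{label}, \code{weight}, \code{phi_mean} (deg),
#'   \code{contact_scale} (multiplier on the base NOE/PRE distances),
#'   \code{cs_shift_h}, \code{cs_shift_c} (sd of the population's
#'   per-restraint chemical-shift offsets, ppm), \code{rdc_shift} (Hz),
#'   \code{rh_mean} (A), \code{fret_dist} (mean CA-CA distance, A),
#'   \code{saxs_rg} (A). Weights must sum to 1.
#' @param counts Named integer vector of restraint counts per data type;
#'   defaults mirror the drkN SH3 unfolded-state set (267 CS, 47 JC, 93
#'   NOE, 68 PRE, 28 RDC, 37 SAXS points, 1 R_h, 1 FRET).
#' @param spreads Within-population conformer variability: \code{cs_h},
#'   \code{cs_c} (ppm), \code{jc_phi} (deg), \code{noe_sdlog},
#'   \code{pre_sdlog}, \code{rdc} (Hz), \code{rh} (A), \code{fret_sdlog},
#'   \code{saxs_sdlog}. Zero spreads make all conformers of a population
#'   identical.
#' @param cfg An \code{uncertainty_config()} (noise sigmas, Karplus priors,
#'   FRET dye model, SAXS grid parameters).
#' @return A list of class \code{"synthetic_truth"}.
#' @export
synthetic_truth <- function(n_pool = 1000L,
                            populations = NULL,
                            counts = c(CS = 267L, JC = 47L, NOE = 93L,
                                       PRE = 68L, RDC = 28L, SAXS = 37L,
                                       RH = 1L, FRET = 1L),
                            spreads = NULL,
                            cfg = uncertainty_config()) {
  if (is.null(populations))
    populations <- list(
      list(label = "A", weight = 0.5, phi_mean = -65, contact_scale = 1.0,
           cs_shift_h = 0.15, cs_shift_c = 1.0, rdc_shift = 1.5,
           rh_mean = 18.5, fret_dist = 45, saxs_rg = 17),
      list(label = "B", weight = 0.5, phi_mean = -120, contact_scale = 1.7,
           cs_shift_h = 0.15, cs_shift_c = 1.0, rdc_shift = 1.5,
           rh_mean = 22.5, fret_dist = 62, saxs_rg = 22))
  w <- vapply(populations, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-9) stop("population weights must sum to 1")
  labs <- vapply(populations, `[[`, character(1), "label")
  if (anyDuplicated(labs)) stop("population labels must be unique")
  def_spreads <- list(cs_h = 0.1, cs_c = 0.8, jc_phi = 15, noe_sdlog = 0.15,
                      pre_sdlog = 0.15, rdc = 1.0, rh = 1.0,
                      fret_sdlog = 0.12, saxs_sdlog = 0.02)
  spreads <- utils::modifyList(def_spreads, spreads %||% list())
  if (any(unlist(spreads) < 0)) stop("spreads must be >= 0")
  structure(list(n_pool = as.integer(n_pool), populations = populations,
                 counts = counts, spreads = spreads, cfg = cfg),
            class = "synthetic_truth")
}

.synth_ids <- function(counts, cfg) {
  atoms <- c("H", "HA", "CA", "CB", "C")
  ncs <- counts[["CS"]]
  res <- rep(seq_len(ceiling(ncs / length(atoms))) + 1L,
             each = length(atoms))[seq_len(ncs)]
  q <- seq(0.01, 0.17, length.out = max(counts[["SAXS"]], 2L))
  list(
    CS = paste0(res, ":", rep_len(atoms, ncs)),
    JC = as.character(seq_len(counts[["JC"]]) + 1L),
    NOE = sprintf("%d.HN-%d.HN", seq_len(counts[["NOE"]]),
                  seq_len(counts[["NOE"]]) + 3L),
    PRE = sprintf("tag14-%d.HN", seq_len(counts[["PRE"]])),
    RDC = as.character(seq_len(counts[["RDC"]]) + 1L),
    SAXS = format(q[seq_len(counts[["SAXS"]])], digits = 10,
                  scientific = FALSE, trim = TRUE),
    RH = "rh",
    FRET = "E1")
}

#' Realize a synthetic conformer pool
#'
#' Draws the per-restraint population means (the restraint-level structure
#' of the "protein") and the per-conformer observables from the truth, and
#' returns back-calculation matrices for every data type plus per-conformer
#' population labels. Bit-identical given the same seed.
#'
#' @param truth A \code{synthetic_truth}.
#' @param seed Integer seed.
#' @return A list of class \code{"synthetic_pool"}: \code{values} (named
#'   list of conformer x restraint matrices; JC holds cos(phi - phi0)),
#'   \code{labels}, \code{pop_means} (per-population mean observables used
#'   to build pseudo-experimental targets), \code{truth}.
#' @export
make_pool <- function(truth, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(seed)
  cfg <- truth$cfg
  counts <- truth$counts
  sp <- truth$spreads
  pops <- truth$populations
  npop <- length(pops)
  plabs <- vapply(pops, `[[`, character(1), "label")
  ids <- .synth_ids(counts, cfg)
  n <- truth$n_pool

  labels <- plabs[sample.int(npop, n, replace = TRUE,
                             prob = vapply(pops, `[[`, numeric(1), "weight"))]
  pop_of <- match(labels, plabs)

  # restraint-level structure shared by all populations
  cs_h <- .cs_is_hydrogen(ids$CS)
  cs_base <- ifelse(cs_h, stats::rnorm(counts[["CS"]], 8.2, 0.4),
                    stats::rnorm(counts[["CS"]], 45, 10))
  noe_base <- stats::runif(counts[["NOE"]], 4, 9)
  pre_base <- stats::runif(counts[["PRE"]], 12, 20)
  rdc_base <- stats::rnorm(counts[["RDC"]], 0, 3)
  qgrid <- as.numeric(ids$SAXS)

  pm <- list()  # per-population per-restraint means
  for (p in seq_len(npop)) {
    pop <- pops[[p]]
    pm[[p]] <- list(
      CS = cs_base + ifelse(cs_h, stats::rnorm(counts[["CS"]], 0, pop$cs_shift_h),
                            stats::rnorm(counts[["CS"]], 0, pop$cs_shift_c)),
      JC_phi = stats::rnorm(counts[["JC"]], pop$phi_mean, 15),
      NOE = noe_base * pop$contact_scale,
      PRE = pre_base * pop$contact_scale,
      RDC = rdc_base + stats::rnorm(counts[["RDC"]], 0, pop$rdc_shift),
      RH = pop$rh_mean,
      FRET_dist = pop$fret_dist,
      SAXS = exp(-(qgrid * pop$saxs_rg)^2 / 3))
  }

  mk <- function(m, fun) {
    out <- matrix(NA_real_, n, m)
    for (p in seq_len(npop)) {
      rows <- which(pop_of == p)
      if (length(rows)) out[rows, ] <- fun(p, length(rows))
    }
    out
  }
  phi0 <- cfg$jc$phi0
  values <- list(
    CS = mk(counts[["CS"]], function(p, k)
      matrix(pm[[p]]$CS, k, counts[["CS"]], byrow = TRUE) +
        matrix(stats::rnorm(k * counts[["CS"]], 0,
                            rep(ifelse(cs_h, sp$cs_h, sp$cs_c), each = k)),
               k, counts[["CS"]])),
    JC = mk(counts[["JC"]], function(p, k) {
      phi <- matrix(pm[[p]]$JC_phi, k, counts[["JC"]], byrow = TRUE) +
        stats::rnorm(k * counts[["JC"]], 0, sp$jc_phi)
      cos((phi - phi0) * pi / 180)
    }),
    NOE = mk(counts[["NOE"]], function(p, k)
      exp(matrix(log(pm[[p]]$NOE), k, counts[["NOE"]], byrow = TRUE) +
            stats::rnorm(k * counts[["NOE"]], 0, sp$noe_sdlog))),
    PRE = mk(counts[["PRE"]], function(p, k)
      exp(matrix(log(pm[[p]]$PRE), k, counts[["PRE"]], byrow = TRUE) +
            stats::rnorm(k * counts[["PRE"]], 0, sp$pre_sdlog))),
    RDC = mk(counts[["RDC"]], function(p, k)
      matrix(pm[[p]]$RDC, k, counts[["RDC"]], byrow = TRUE) +
        stats::rnorm(k * counts[["RDC"]], 0, sp$rdc)),
    RH = mk(counts[["RH"]], function(p, k)
      matrix(pm[[p]]$RH + stats::rnorm(k, 0, sp$rh), k, counts[["RH"]])),
    FRET = mk(counts[["FRET"]], function(p, k) {
      r <- exp(log(pm[[p]]$FRET_dist) + stats::rnorm(k, 0, sp$fret_sdlog))
      rda <- fret_distance_scaled(r, cfg$fret$n_res, cfg$fret$n_linker,
                                  cfg$fret$upsilon)
      matrix(fret_efficiency(rda, cfg$fret$r0), k, counts[["FRET"]])
    }),
    SAXS = mk(counts[["SAXS"]], function(p, k)
      exp(matrix(log(pm[[p]]$SAXS), k, counts[["SAXS"]], byrow = TRUE) +
            stats::rnorm(k * counts[["SAXS"]], 0, sp$saxs_sdlog))))
  for (tp in names(values)) colnames(values[[tp]]) <- ids[[tp]]

  structure(list(values = values, labels = labels, pop_means = pm,
                 pop_labels = plabs, ids = ids, truth = truth),
            class = "synthetic_pool")
}

# empirical per-population averaging with the per-type conventions:
# NOE/PRE combine pop means of d^-6 then back-transform; JC combines the
# cosine means then maps through the prior-mean Karplus curve; all others
# are linear averages of the population means
.mixture_targets <- function(pool, weights, cfg) {
  labs <- pool$pop_labels
  w <- weights[labs]
  if (anyNA(w)) stop("target weights must be named by population label")
  if (abs(sum(w) - 1) > 1e-9) stop("target weights must sum to 1")
  popmean <- function(m, transform = identity) {
    out <- matrix(0, length(labs), ncol(m))
    for (p in seq_along(labs)) {
      rows <- pool$labels == labs[p]
      if (!any(rows)) {
        if (w[p] > 0)
          stop("population '", labs[p], "' has positive target weight but ",
               "no realized conformers")
        next  # zero-weight empty population contributes nothing
      }
      out[p, ] <- colMeans(transform(m[rows, , drop = FALSE]))
    }
    out
  }
  combine <- function(pm) as.numeric(crossprod(w, pm))
  tg <- list()
  tg$CS <- combine(popmean(pool$values$CS))
  a1 <- combine(popmean(pool$values$JC))
  a2 <- combine(popmean(pool$values$JC, function(x) x^2))
  tg$JC <- cfg$jc$mu_A * a2 + cfg$jc$mu_B * a1 + cfg$jc$mu_C
  tg$NOE <- combine(popmean(pool$values$NOE, function(x) x^-6))^(-1 / 6)
  tg$PRE <- combine(popmean(pool$values$PRE, function(x) x^-6))^(-1 / 6)
  tg$RDC <- combine(popmean(pool$values$RDC))
  tg$RH <- combine(popmean(pool$values$RH))
  tg$FRET <- combine(popmean(pool$values$FRET))
  tg$SAXS <- combine(popmean(pool$values$SAXS))
  tg
}

#' Generate pseudo-experimental restraints from a synthetic pool
#'
#' Each target is the ensemble average, under the requested population
#' weights, of the empirical per-population observables (r^-6 convention
#' for NOE/PRE, efficiency averaging for FRET, prior-mean Karplus mapping
#' for JC), plus optional Gaussian noise at the per-type experimental
#' uncertainty. When the target weights equal the realized pool label
#' frequencies and noise is off, scoring the full pool recovers every
#' target exactly (all residuals zero).
#'
#' @param pool A \code{synthetic_pool}.
#' @param target_weights Named numeric vector of ground-truth mixture
#'   weights (names = population labels, summing to 1).
#' @param noise Add Gaussian noise at sigma_ex (default TRUE).
#' @param seed Integer seed for the noise draws.
#' @return Named list of \code{restraint_set}s with attribute
#'   \code{"target_weights"}.
#' @export
make_experimental <- function(pool, target_weights, noise = TRUE,
                              seed = 1L) {
  stopifnot(inherits(pool, "synthetic_pool"))
  cfg <- pool$truth$cfg
  counts <- pool$truth$counts
  tg <- .mixture_targets(pool, target_weights, cfg)
  q <- as.numeric(pool$ids$SAXS)
  sig <- list(
    CS = ifelse(.cs_is_hydrogen(pool$ids$CS), cfg$cs$sigma_ex_h,
                cfg$cs$sigma_ex_c),
    JC = rep(cfg$jc$sigma_ex, counts[["JC"]]),
    NOE = rep_len(c(4, 5), counts[["NOE"]]),
    PRE = rep((25 - 10) / cfg$pre$range_divisor, counts[["PRE"]]),
    RDC = rep(cfg$rdc$sigma_ex, counts[["RDC"]]),
    RH = rep(cfg$rh$sigma_ex, counts[["RH"]]),
    FRET = rep(cfg$fret$sigma_ex, counts[["FRET"]]),
    SAXS = cfg$saxs$sigma_ex_hi + (cfg$saxs$sigma_ex_lo - cfg$saxs$sigma_ex_hi) *
      (q - min(q)) / (max(q) - min(q)))
  if (noise) set.seed(seed)
  out <- list()
  for (tp in names(tg)) {
    target <- tg[[tp]]
    if (noise) target <- target + stats::rnorm(length(target), 0, sig[[tp]])
    out[[tp]] <- restraint_set(id = pool$ids[[tp]], target = target,
                               datatype = tp, sigma_exp = sig[[tp]],
                               cfg = cfg)
  }
  attr(out, "target_weights") <- target_weights
  out
}

#' Assemble a scoring context from synthetic fixtures
#'
#' Pairs the pool's observable matrices with pseudo-experimental restraint
#' sets into aligned \code{backcalc_table}s and a \code{scoring_context}
#' carrying the population labels.
#'
#' @param pool A \code{synthetic_pool}.
#' @param restraints Output of \code{make_experimental} (or a subset of its
#'   types).
#' @param active Data types in the objective (default: all present).
#' @return A \code{scoring_context}.
#' @export
synthetic_context <- function(pool, restraints, active = NULL) {
  stopifnot(inherits(pool, "synthetic_pool"))
  cfg <- pool$truth$cfg
  tables <- lapply(names(restraints), function(tp)
    backcalc_table(pool$values[[tp]], tp, restraints[[tp]]))
  names(tables) <- names(restraints)
  scoring_context(restraints, tables, cfg, active = active,
                  labels = pool$labels)
}

#' Write synthetic fixtures to disk
#'
#' Writes the restraint and back-calculation tables of a synthetic study in
#' the same TSV formats consumed by the loaders, so generated fixtures are
#' indistinguishable from real inputs.
#'
#' @param pool A \code{synthetic_pool}.
#' @param restraints Output of \code{make_experimental}.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_fixtures <- function(pool, restraints, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tp in names(restraints)) {
    write_restraints(restraints[[tp]],
                     file.path(dir, paste0(tolower(tp), "_restraints.tsv")))
    tab <- backcalc_table(pool$values[[tp]], tp, restraints[[tp]])
    write_backcalc(tab, file.path(dir, paste0(tolower(tp), "_backcalc.tsv")))
  }
  writeLines(pool$labels, file.path(dir, "labels.txt"))
  invisible(dir)
}
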