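# Gaussian log-density with explicit normalization constant; the scores are
# absolute log-likelihoods, so the -log(sigma*sqrt(2*pi)) terms are kept.
.ldnorm <- function(x, sd) -0.918938533204672742 - log(sd) - 0.5 * (x / sd)^2

#' Optimized Gaussian offset nuisance model
#'
#' The generic two-Gaussian model used for chemical shifts, NOE/PRE
#' distances, RDCs, hydrodynamic radius, FRET efficiency and individual
#' SAXS intensity points: the back-calculation offset q has prior
#' N(0, sigma_q) and the residual eps = target - q - ens_avg has likelihood
#' N(0, sigma_ex). Their joint log-density is maximized over q in closed
#' form:
#' \deqn{q* = \sigma_q^2 (target - \langle o \rangle) / (\sigma_q^2 + \sigma_{ex}^2)}
#' with eps* = target - q* - ens_avg, and logp the sum of the two Gaussian
#' log-densities at the optimum (normalization constants included). With
#' sigma_q = 0 the offset is pinned at q = 0 and only the residual term is
#' scored.
#'
#' @param target Experimental value.
#' @param ens_avg Ensemble-averaged back-calculated value.
#' @param sigma_q Back-calculation uncertainty (>= 0).
#' @param sigma_ex Experimental uncertainty (> 0).
#' @return A list of class \code{"nuisance_solution"} with fields
#'   \code{q_star}, \code{eps_star}, \code{logp}. The optimum satisfies the
#'   stationarity identity q* sigma_ex^2 = eps* sigma_q^2.
#' @export
optimize_offset <- function(target, ens_avg, sigma_q, sigma_ex) {
  if (sigma_ex <= 0) stop("sigma_ex must be > 0")
  if (sigma_q < 0) stop("sigma_q must be >= 0")
  sol <- .offset_solve(target - ens_avg, sigma_q, sigma_ex)
  structure(list(q_star = sol$q, eps_star = sol$eps, logp = sol$logp),
            class = "nuisance_solution")
}

# vectorized closed form; delta = target - ensemble average
.offset_solve <- function(delta, sigma_q, sigma_ex) {
  denom <- sigma_q^2 + sigma_ex^2
  q <- ifelse(sigma_q > 0, sigma_q^2 * delta / denom, 0)
  eps <- delta - q
  logp <- ifelse(sigma_q > 0,
                 .ldnorm(q, sigma_q) + .ldnorm(eps, sigma_ex),
                 .ldnorm(eps, sigma_ex))
  list(q = q, eps = eps, logp = logp)
}

#' Optimized Karplus nuisance model for J-couplings
#'
#' The J-coupling model treats the three Karplus coefficients as Gaussian
#' random variables A ~ N(mu_A, sigma_A), B ~ N(mu_B, sigma_B),
#' C ~ N(mu_C, sigma_C) and the residual
#' eps = J_exp - (A a2 + B a1 + C) as N(0, sigma_ex), where a1 = <cos(phi -
#' phi0)> and a2 = <cos^2(phi - phi0)> are ensemble averages. The
#' four-Gaussian objective is quadratic in (A, B, C) and maximized in closed
#' form: with eps0 = J - (mu_A a2 + mu_B a1 + mu_C),
#' S = sigma_A^2 a2^2 + sigma_B^2 a1^2 + sigma_C^2 and
#' k = eps0 / (sigma_ex^2 + S),
#' \deqn{A* = \mu_A + \sigma_A^2 a_2 k,\quad B* = \mu_B + \sigma_B^2 a_1 k,
#'   \quad C* = \mu_C + \sigma_C^2 k,\quad \epsilon* = \sigma_{ex}^2 k.}
#'
#' @param a1 Ensemble mean of cos(phi - phi0), in [-1, 1].
#' @param a2 Ensemble mean of cos^2(phi - phi0), in [0, 1] with a2 >= a1^2.
#' @param target_j Experimental J-coupling (Hz).
#' @param karplus List with fields mu_A, sigma_A, mu_B, sigma_B, mu_C,
#'   sigma_C (e.g. \code{uncertainty_config()$jc}).
#' @param sigma_ex Experimental uncertainty (Hz).
#' @return A \code{"nuisance_solution"} with fields \code{A_star},
#'   \code{B_star}, \code{C_star}, \code{eps_star}, \code{logp}.
#' @export
optimize_karplus <- function(a1, a2, target_j, karplus, sigma_ex) {
  if (sigma_ex <= 0) stop("sigma_ex must be > 0")
  if (a1 < -1 - 1e-12 || a1 > 1 + 1e-12) stop("a1 must lie in [-1, 1]")
  if (a2 < 0 || a2 > 1 + 1e-12) stop("a2 must lie in [0, 1]")
  if (a2 < a1^2 - 1e-9) stop("a2 >= a1^2 violated (Jensen inequality)")
  sol <- .karplus_solve(a1, a2, target_j, karplus, sigma_ex)
  structure(list(A_star = sol$A, B_star = sol$B, C_star = sol$C,
                 eps_star = sol$eps, logp = sol$logp),
            class = "nuisance_solution")
}

# vectorized over restraints
.karplus_solve <- function(a1, a2, target_j, kp, sigma_ex) {
  eps0 <- target_j - (kp$mu_A * a2 + kp$mu_B * a1 + kp$mu_C)
  S <- kp$sigma_A^2 * a2^2 + kp$sigma_B^2 * a1^2 + kp$sigma_C^2
  k <- eps0 / (sigma_ex^2 + S)
  A <- kp$mu_A + kp$sigma_A^2 * a2 * k
  B <- kp$mu_B + kp$sigma_B^2 * a1 * k
  C <- kp$mu_C + kp$sigma_C^2 * k
  eps <- sigma_ex^2 * k
  logp <- .ldnorm(A - kp$mu_A, kp$sigma_A) + .ldnorm(B - kp$mu_B, kp$sigma_B) +
    .ldnorm(C - kp$mu_C, kp$sigma_C) + .ldnorm(eps, sigma_ex)
  list(A = A, B = B, C = C, eps = eps, logp = logp)
}

#' r^-6 ensemble-averaged distance
#'
#' The NOE/PRE ensemble average: (mean of d_i^-6)^(-1/6). The result lies
#' between the minimum and maximum distance, weighted toward the minimum,
#' reflecting the r^-6 dependence of the underlying relaxation observables.
#'
#' @param distances Positive distances (Angstrom), non-empty.
#' @return Ensemble-averaged distance (Angstrom).
#' @export
ensemble_average_distance <- function(distances) {
  if (length(distances) == 0L) stop("empty distance list")
  if (any(distances <= 0)) stop("distances must be > 0")
  mean(distances^-6)^(-1 / 6)
}

#' Number of Shannon channels of a SAXS curve
#'
#' N_s = D_max (q_max - q_min) / pi: the effective number of independent
#' observations in a scattering curve for a particle of maximum dimension
#' D_max, used to down-weight oversampled SAXS grids.
#'
#' @param d_max Maximum particle dimension (Angstrom, >= 0).
#' @param q_min,q_max Momentum-transfer range (1/Angstrom, q_max > q_min >= 0).
#' @return N_s (real, not rounded).
#' @export
shannon_channels <- function(d_max, q_min, q_max) {
  if (q_max <= q_min) stop("q_max must exceed q_min")
  if (q_min < 0 || d_max < 0) stop("q_min and d_max must be >= 0")
  d_max * (q_max - q_min) / pi
}

.saxs_weight <- function(restraints, cfg) {
  nq <- nrow(restraints)
  ns <- cfg$saxs$ns_override
  if (is.na(ns)) {
    q <- as.numeric(restraints$id)
    qmin <- if (is.na(cfg$saxs$q_min)) min(q) else cfg$saxs$q_min
    qmax <- if (is.na(cfg$saxs$q_max)) max(q) else cfg$saxs$q_max
    ns <- shannon_channels(cfg$saxs$d_max, qmin, qmax)
  }
  if (ns <= 0) stop("number of Shannon channels must be > 0")
  min(1, ns / nq)
}

# --- ensemble averaging from member indices -------------------------------

.members_of <- function(state_or_members) {
  if (inherits(state_or_members, "ensemble_state")) state_or_members$members
  else as.integer(state_or_members)
}

# per-conformer contribution matrix whose column means feed the score:
# raw values for linear averages, d^-6 for NOE/PRE; JC keeps two matrices
.contrib <- function(tab) {
  switch(tab$datatype,
    NOE = tab$values^-6,
    PRE = tab$values^-6,
    JC = list(cos = tab$values, cos2 = tab$cos2),
    tab$values)
}

.sums_over <- function(contrib, members) {
  if (is.list(contrib))
    list(cos = colSums(contrib$cos[members, , drop = FALSE]),
         cos2 = colSums(contrib$cos2[members, , drop = FALSE]))
  else colSums(contrib[members, , drop = FALSE])
}

# ensemble-averaged observable from running sums (NOE/PRE: back-transformed)
.avg_from_sums <- function(datatype, sums, n) {
  if (datatype %in% c("NOE", "PRE")) (sums / n)^(-1 / 6)
  else sums / n
}

# total logp (and optional per-restraint detail) from running sums
.score_from_sums <- function(datatype, restraints, sums, n, cfg,
                             detail = FALSE) {
  if (datatype == "JC") {
    sol <- .karplus_solve(sums$cos / n, sums$cos2 / n, restraints$target,
                          cfg$jc, restraints$sigma_exp)
    per <- if (detail)
      data.frame(id = restraints$id, A_star = sol$A, B_star = sol$B,
                 C_star = sol$C, eps_star = sol$eps, logp = sol$logp)
    return(list(total = sum(sol$logp), per_restraint = per, weight = 1))
  }
  avg <- .avg_from_sums(datatype, sums, n)
  sol <- .offset_solve(restraints$target - avg, restraints$sigma_q,
                       restraints$sigma_exp)
  weight <- 1
  logp <- sol$logp
  if (datatype == "SAXS") {
    weight <- .saxs_weight(restraints, cfg)
    if (identical(cfg$saxs$weight_mode, "residual")) {
      # scale only the chi^2 part, keep normalization constants unscaled
      const <- ifelse(restraints$sigma_q > 0,
                      .ldnorm(0, restraints$sigma_q), 0) +
        .ldnorm(0, restraints$sigma_exp)
      logp <- const + weight * (logp - const)
      return(list(total = sum(logp),
                  per_restraint = if (detail)
                    data.frame(id = restraints$id, q_star = sol$q,
                               eps_star = sol$eps, logp = logp),
                  weight = weight))
    }
  }
  per <- if (detail)
    data.frame(id = restraints$id, q_star = sol$q, eps_star = sol$eps,
               logp = logp)
  list(total = weight * sum(logp), per_restraint = per, weight = weight)
}

#' Score one data type for an ensemble
#'
#' Computes the ensemble-averaged observables of the members (arithmetic
#' mean for CS / JC cosine terms / RDC / R_h / FRET efficiency / SAXS
#' intensity; r^-6 mean for NOE/PRE distances), then optimizes the Gaussian
#' nuisance parameters per restraint (offset model, or the Karplus triple
#' for JC) and sums the per-restraint maximum log-likelihoods. SAXS totals
#' are multiplied by the Shannon weight min(1, N_s / N_q).
#'
#' @param restraints A \code{restraint_set}.
#' @param table The aligned \code{backcalc_table}.
#' @param state An \code{ensemble_state} or an integer vector of member
#'   indices into the table's conformers (duplicates allowed).
#' @param cfg An \code{uncertainty_config()}.
#' @return A list of class \code{"type_score"}: \code{datatype},
#'   \code{total} (log-likelihood), \code{per_restraint} (data frame of
#'   nuisance solutions), \code{weight} (Shannon factor, 1 except SAXS),
#'   \code{rmsd} (per the deviation metric; absolute deviation when only
#'   one restraint).
#' @export
score_type <- function(restraints, table, state, cfg = uncertainty_config()) {
  stopifnot(inherits(restraints, "restraint_set"),
            inherits(table, "backcalc_table"))
  datatype <- attr(restraints, "datatype")
  if (table$datatype != datatype)
    stop("datatype mismatch: restraints ", datatype, " vs table ",
         table$datatype)
  if (!identical(table$restraint_ids, restraints$id))
    stop("back-calculation table is not aligned to the restraint set")
  members <- .members_of(state)
  if (length(members) &&
      (min(members) < 1L || max(members) > nrow(table$values)))
    stop("member index out of range")
  if (nrow(restraints) == 0L)
    return(structure(list(datatype = datatype, total = 0,
                          per_restraint = NULL, weight = 1, rmsd = NA_real_),
                     class = "type_score"))
  if (length(members) == 0L) stop("empty ensemble")
  contrib <- .contrib(table)
  sums <- .sums_over(contrib, members)
  sc <- .score_from_sums(datatype, restraints, sums, length(members), cfg,
                         detail = TRUE)
  calc <- if (datatype == "JC")
    cfg$jc$mu_A * sums$cos2 / length(members) +
      cfg$jc$mu_B * sums$cos / length(members) + cfg$jc$mu_C
  else .avg_from_sums(datatype, sums, length(members))
  structure(list(datatype = datatype, total = sc$total,
                 per_restraint = sc$per_restraint, weight = sc$weight,
                 rmsd = rmsd(calc, restraints$target)),
            class = "type_score")
}

#' Score a SAXS curve with Shannon-channel weighting
#'
#' Convenience wrapper around \code{score_type} for SAXS restraint sets:
#' each intensity point is scored with the offset model and the per-point
#' sum is multiplied by min(1, N_s / N_q), so an oversampled curve cannot
#' overwhelm data types with few observations. N_s comes from
#' \code{shannon_channels(d_max, q_min, q_max)} on the restraint Q grid
#' unless \code{cfg$saxs$ns_override} is set.
#'
#' @inheritParams score_type
#' @return A \code{"type_score"} with the applied weight recorded.
#' @export
score_saxs <- function(restraints, table, state, cfg = uncertainty_config()) {
  if (attr(restraints, "datatype") != "SAXS")
    stop("score_saxs expects SAXS restraints")
  score_type(restraints, table, state, cfg)
}

#' Total objective over data types
#'
#' Sum of per-type log-likelihood totals over the active data types;
#' inactive types remain reported in their \code{type_score}s but do not
#' enter the optimization objective.
#'
#' @param type_scores List of \code{type_score} objects (or a named numeric
#'   vector of totals).
#' @param active Character vector of data types to include (default: all
#'   present).
#' @return Total log-likelihood (0 for an empty active set).
#' @export
total_score <- function(type_scores, active = NULL) {
  if (is.numeric(type_scores)) {
    totals <- type_scores
  } else {
    totals <- vapply(type_scores, function(s) s$total, numeric(1))
    names(totals) <- vapply(type_scores, function(s) s$datatype, character(1))
  }
  if (is.null(active)) active <- names(totals)
  sum(totals[names(totals) %in% active])
}

#' Upper bound of the score of a scoring context
#'
#' The analytic maximum of the total log-likelihood: the sum, over
#' restraints, of each Gaussian component's log-density peak (all residuals
#' and offsets zero), with the SAXS Shannon weight applied. Scoring can
#' reach this bound only when every ensemble-averaged observable matches
#' its target exactly.
#'
#' @param ctx A \code{scoring_context}.
#' @param active Data types to include (default: the context's active set).
#' @return Upper bound on the total score.
#' @export
score_upper_bound <- function(ctx, active = NULL) {
  stopifnot(inherits(ctx, "scoring_context"))
  if (is.null(active)) active <- ctx$active
  tot <- 0
  for (tp in active) {
    d <- ctx$types[[tp]]
    rs <- d$restraints
    peak <- if (tp == "JC") {
      kp <- ctx$cfg$jc
      sum(.ldnorm(0, kp$sigma_A) + .ldnorm(0, kp$sigma_B) +
            .ldnorm(0, kp$sigma_C) + .ldnorm(0, rs$sigma_exp))
    } else {
      sum(ifelse(rs$sigma_q > 0, .ldnorm(0, rs$sigma_q), 0) +
            .ldnorm(0, rs$sigma_exp))
    }
    if (tp == "SAXS") peak <- peak * .saxs_weight(rs, ctx$cfg)
    tot <- tot + peak
  }
  tot
}

#' @export
print.nuisance_solution <- function(x, ...) {
  cat("nuisance_solution:",
      paste(names(x), signif(unlist(x), 6), sep = " = ", collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
print.type_score <- function(x, ...) {
  cat(sprintf("type_score %s: total logp = %.4f, rmsd = %.4g%s\n",
              x$datatype, x$total, x$rmsd,
              if (x$weight != 1) sprintf(" (Shannon weight %.4g)", x$weight)
              else ""))
  invisible(x)
}
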