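#' Build a scoring context
#'
#' Bundles the aligned restraint sets and back-calculation tables of one
#' study, pre-computes the per-conformer contribution matrices used by the
#' incremental swap updates (raw values for linearly averaged types, d^-6
#' for NOE/PRE, the two cosine matrices for JC) and fixes the active data
#' types entering the optimization objective.
#'
#' @param restraints Named list of \code{restraint_set}s (names = data
#'   types).
#' @param tables Named list of matching \code{backcalc_table}s.
#' @param cfg An \code{uncertainty_config()}.
#' @param active Data types included in the objective (default: all).
#' @param labels Optional per-conformer population labels (length = pool
#'   size).
#' @return A list of class \code{"scoring_context"}.
#' @export
scoring_context <- function(restraints, tables, cfg = uncertainty_config(),
                            active = NULL, labels = NULL) {
  types <- names(restraints)
  if (is.null(types) || !all(types %in% DATATYPES))
    stop("restraints must be a named list keyed by data type")
  if (!setequal(types, names(tables)))
    stop("restraints and tables must cover the same data types")
  n_pool <- NULL
  built <- list()
  for (tp in types) {
    rs <- restraints[[tp]]
    tab <- tables[[tp]]
    stopifnot(inherits(rs, "restraint_set"), inherits(tab, "backcalc_table"))
    if (attr(rs, "datatype") != tp || tab$datatype != tp)
      stop("datatype mismatch for '", tp, "'")
    if (!identical(tab$restraint_ids, rs$id))
      stop("table for '", tp, "' is not aligned to its restraint set")
    np <- nrow(tab$values)
    if (is.null(n_pool)) n_pool <- np
    else if (np != n_pool)
      stop("all back-calculation tables must cover the same conformer pool")
    built[[tp]] <- list(restraints = rs, table = tab, contrib = .contrib(tab))
  }
  if (is.null(active)) active <- types
  if (!all(active %in% types))
    stop("active types absent from the context: ",
         paste(setdiff(active, types), collapse = ", "))
  if (!is.null(labels) && length(labels) != n_pool)
    stop("labels must be given for every pool conformer")
  structure(list(types = built, active = active, cfg = cfg,
                 n_pool = n_pool, labels = labels),
            class = "scoring_context")
}

#' Draw a random sub-ensemble
#'
#' N uniform draws with replacement from the pool (the same conformer may be
#' selected any number of times); reproducible given a seed.
#'
#' @param pool_size Number of conformers in the pool (>= 1).
#' @param n Sub-ensemble size (>= 1).
#' @param seed Optional integer seed.
#' @return Integer vector of member indices (a multiset).
#' @export
sample_subensemble <- function(pool_size, n, seed = NULL) {
  if (pool_size < 1L) stop("empty pool")
  if (n < 1L) stop("sub-ensemble size must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  sample.int(pool_size, n, replace = TRUE)
}

#' Construct an ensemble state
#'
#' An ensemble state is a size-N multiset of conformer indices with cached
#' per-restraint running sums of back-calculated observables (sums of d^-6
#' for NOE/PRE), per-type scores, and the total objective over the active
#' types. The cache makes a conformer swap O(restraints), independent of N.
#'
#' @param ctx A \code{scoring_context}.
#' @param members Integer vector of member indices into the pool.
#' @return A list of class \code{"ensemble_state"}.
#' @export
ensemble_state <- function(ctx, members) {
  stopifnot(inherits(ctx, "scoring_context"))
  members <- as.integer(members)
  if (length(members) == 0L) stop("empty ensemble")
  if (min(members) < 1L || max(members) > ctx$n_pool)
    stop("member index out of range")
  sums <- lapply(ctx$types, function(d) .sums_over(d$contrib, members))
  st <- list(members = members, n = length(members), sums = sums)
  .rescore_state(ctx, st)
}

.rescore_state <- function(ctx, st) {
  totals <- vapply(names(ctx$types), function(tp)
    .score_from_sums(tp, ctx$types[[tp]]$restraints, st$sums[[tp]], st$n,
                     ctx$cfg)$total, numeric(1))
  st$type_totals <- totals
  st$total <- sum(totals[ctx$active])
  class(st) <- "ensemble_state"
  st
}

#' Verify the cached sums of a state
#'
#' Recomputes the running sums and objective from scratch and reports the
#' largest absolute discrepancy against the cache.
#'
#' @param state An \code{ensemble_state}.
#' @param ctx Its \code{scoring_context}.
#' @return List with \code{max_sum_error}, \code{total_error} and a fresh
#'   \code{state}.
#' @export
audit_state <- function(state, ctx) {
  fresh <- ensemble_state(ctx, state$members)
  errs <- vapply(names(ctx$types), function(tp) {
    a <- state$sums[[tp]]; b <- fresh$sums[[tp]]
    if (is.list(a)) max(abs(a$cos - b$cos), abs(a$cos2 - b$cos2))
    else max(abs(a - b))
  }, numeric(1))
  list(max_sum_error = max(errs),
       total_error = abs(state$total - fresh$total),
       state = fresh)
}

#' Propose a conformer swap
#'
#' Uniformly picks one member position to replace and one pool conformer to
#' bring in (possibly one already in the ensemble: multiset semantics). The
#' state itself is not modified.
#'
#' @param state An \code{ensemble_state}.
#' @param ctx Its \code{scoring_context}.
#' @return List \code{(out_position, in_pool_index)}.
#' @export
propose_swap <- function(state, ctx) {
  list(out_position = sample.int(state$n, 1L),
       in_pool_index = sample.int(ctx$n_pool, 1L))
}

#' Apply a swap with incremental score update
#'
#' Replaces the member at \code{out_position} by pool conformer
#' \code{in_pool_index}, updating the cached running sums by subtracting the
#' outgoing conformer's contributions and adding the incoming one's, then
#' recomputing the per-type scores from the updated averages. Cost per
#' restraint is independent of the ensemble size N.
#'
#' @param state An \code{ensemble_state}.
#' @param ctx Its \code{scoring_context}.
#' @param out_position Member position to vacate (1..N).
#' @param in_pool_index Incoming pool conformer (1..pool size).
#' @return The updated \code{ensemble_state}.
#' @export
apply_swap_incremental <- function(state, ctx, out_position, in_pool_index) {
  if (out_position < 1L || out_position > state$n)
    stop("out_position out of range")
  if (in_pool_index < 1L || in_pool_index > ctx$n_pool)
    stop("in_pool_index out of range")
  out_idx <- state$members[out_position]
  for (tp in names(ctx$types)) {
    co <- ctx$types[[tp]]$contrib
    if (is.list(co)) {
      state$sums[[tp]]$cos <- state$sums[[tp]]$cos +
        co$cos[in_pool_index, ] - co$cos[out_idx, ]
      state$sums[[tp]]$cos2 <- state$sums[[tp]]$cos2 +
        co$cos2[in_pool_index, ] - co$cos2[out_idx, ]
    } else {
      state$sums[[tp]] <- state$sums[[tp]] +
        co[in_pool_index, ] - co[out_idx, ]
    }
  }
  state$members[out_position] <- as.integer(in_pool_index)
  .rescore_state(ctx, state)
}

#' Greedy acceptance rule
#'
#' Accept only strictly score-increasing exchanges (ties rejected).
#'
#' @param score_old,score_new Objective before/after the proposed swap.
#' @return Logical.
#' @export
accept_greedy <- function(score_old, score_new) score_new > score_old

#' Metropolis acceptance rule
#'
#' Accept with probability min(1, exp(beta * (score_new - score_old)));
#' uphill moves are always accepted, downhill moves with the Boltzmann-like
#' probability controlled by the hyperparameter beta.
#'
#' @param score_old,score_new Objectives.
#' @param beta Inverse-temperature-like hyperparameter (> 0; 0.1 yields
#'   roughly 50 percent acceptance in the reference study conditions).
#' @return Logical.
#' @export
accept_metropolis <- function(score_old, score_new, beta = 0.1) {
  if (beta <= 0) stop("beta must be > 0")
  delta <- score_new - score_old
  delta > 0 || stats::runif(1) < exp(beta * delta)
}

#' Optimizer configuration
#'
#' @param n_steps Number of exchange attempts (default 10000).
#' @param mode "greedy" (strictly increasing acceptance) or "metropolis".
#' @param beta Metropolis hyperparameter (default 0.1).
#' @param ensemble_size Sub-ensemble size N (default 100).
#' @param n_replicates Number of independently drawn and optimized
#'   sub-ensembles (default 1000).
#' @param refresh_every Recompute the running-sum cache from scratch after
#'   this many accepted swaps, bounding floating-point drift (default 1000).
#' @return A list of class \code{"optimizer_config"}.
#' @export
optimizer_config <- function(n_steps = 10000L,
                             mode = c("greedy", "metropolis"),
                             beta = 0.1, ensemble_size = 100L,
                             n_replicates = 1000L, refresh_every = 1000L) {
  mode <- match.arg(mode)
  if (n_steps < 0L) stop("n_steps must be >= 0")
  if (mode == "metropolis" && beta <= 0) stop("beta must be > 0")
  structure(list(n_steps = as.integer(n_steps), mode = mode, beta = beta,
                 ensemble_size = as.integer(ensemble_size),
                 n_replicates = as.integer(n_replicates),
                 refresh_every = as.integer(refresh_every)),
            class = "optimizer_config")
}

#' Run one Monte Carlo conformer-swap optimization
#'
#' Performs \code{opt$n_steps} exchange attempts: each step proposes
#' replacing a uniformly chosen member with a uniformly chosen pool
#' conformer, scores the proposal incrementally, and accepts per the
#' configured rule (greedy: strictly increasing; metropolis: min(1,
#' exp(beta * delta))). The running-sum cache is rebuilt from scratch every
#' \code{opt$refresh_every} accepted swaps to bound floating-point drift.
#'
#' @param ctx A \code{scoring_context}.
#' @param opt An \code{optimizer_config}.
#' @param state Initial \code{ensemble_state} (default: a fresh uniform
#'   draw).
#' @return List with the final \code{state}, the objective \code{trace}
#'   (value after every attempt, length n_steps), \code{initial_total} and
#'   \code{n_accepted}. In greedy mode the final objective is >= the
#'   initial one.
#' @export
run_optimization <- function(ctx, opt = optimizer_config(), state = NULL) {
  stopifnot(inherits(ctx, "scoring_context"))
  if (is.null(state))
    state <- ensemble_state(ctx, sample_subensemble(ctx$n_pool,
                                                    opt$ensemble_size))
  initial_total <- state$total
  n_steps <- opt$n_steps
  trace <- numeric(n_steps)
  n_accepted <- 0L
  accepted_since_refresh <- 0L
  greedy <- opt$mode == "greedy"
  if (n_steps > 0L) for (step in seq_len(n_steps)) {
    prop <- propose_swap(state, ctx)
    cand <- apply_swap_incremental(state, ctx, prop$out_position,
                                   prop$in_pool_index)
    ok <- if (greedy) accept_greedy(state$total, cand$total)
          else accept_metropolis(state$total, cand$total, opt$beta)
    if (ok) {
      state <- cand
      n_accepted <- n_accepted + 1L
      accepted_since_refresh <- accepted_since_refresh + 1L
      if (accepted_since_refresh >= opt$refresh_every) {
        state <- ensemble_state(ctx, state$members)
        accepted_since_refresh <- 0L
      }
    }
    trace[step] <- state$total
  }
  list(state = state, trace = trace, initial_total = initial_total,
       n_accepted = n_accepted)
}

#' Run independent optimization replicates
#'
#' Draws \code{opt$n_replicates} fresh random sub-ensembles (independent
#' seeds spawned from the master seed via the Mersenne-Twister stream),
#' optimizes each, and aggregates per-type scores and deviation metrics as
#' replicate mean and sample standard deviation — the mean (sd) presentation
#' used to report ensemble evaluations.
#'
#' @param ctx A \code{scoring_context}.
#' @param opt An \code{optimizer_config}.
#' @param master_seed Integer master seed; the whole run is a pure function
#'   of (inputs, master seed).
#' @return List of class \code{"replicate_run"}: \code{replicates} (each
#'   with members, total, type_totals, rmsd, initial counterparts),
#'   \code{summary} (per-type mean/sd of scores and RMSDs, optimized and
#'   unoptimized), \code{composition} (mean label fractions, if the context
#'   has labels), \code{rng} (algorithm and seeds).
#' @export
run_replicates <- function(ctx, opt = optimizer_config(), master_seed = 1L) {
  stopifnot(inherits(ctx, "scoring_context"))
  if (opt$n_replicates < 1L) stop("n_replicates must be >= 1")
  set.seed(master_seed)
  seeds <- sample.int(.Machine$integer.max, opt$n_replicates)
  reps <- vector("list", opt$n_replicates)
  for (r in seq_len(opt$n_replicates)) {
    set.seed(seeds[r])
    st0 <- ensemble_state(ctx, sample_subensemble(ctx$n_pool,
                                                  opt$ensemble_size))
    res <- run_optimization(ctx, opt, st0)
    reps[[r]] <- list(
      seed = seeds[r],
      members = res$state$members,
      total = res$state$total,
      type_totals = res$state$type_totals,
      rmsd = state_rmsd(res$state, ctx),
      initial_total = res$initial_total,
      initial_type_totals = st0$type_totals,
      initial_rmsd = state_rmsd(st0, ctx),
      n_accepted = res$n_accepted)
  }
  types <- names(ctx$types)
  grab <- function(field) {
    v <- vapply(reps, function(x) x[[field]], numeric(length(types)))
    if (length(types) == 1L) matrix(v, ncol = 1L) else t(v)
  }
  summ <- list()
  for (what in c("type_totals", "rmsd", "initial_type_totals",
                 "initial_rmsd")) {
    m <- grab(what)
    colnames(m) <- types
    summ[[what]] <- data.frame(
      datatype = types,
      mean = colMeans(m),
      sd = apply(m, 2L, function(v) if (length(v) > 1L) stats::sd(v)
                 else NA_real_),
      row.names = NULL)
  }
  comp <- if (!is.null(ctx$labels))
    pool_composition(lapply(reps, `[[`, "members"), ctx$labels)
  structure(list(replicates = reps, summary = summ, composition = comp,
                 rng = list(algorithm = RNGkind()[1], master_seed = master_seed,
                            replicate_seeds = seeds),
                 opt = opt, active = ctx$active),
            class = "replicate_run")
}

#' Deviation metrics of a state, per data type
#'
#' Root-mean-square deviation between ensemble-averaged back-calculated
#' observables and the experimental targets, per data type (absolute
#' deviation for single-restraint types such as R_h and mean FRET
#' efficiency).
#'
#' @param state An \code{ensemble_state}.
#' @param ctx Its \code{scoring_context}.
#' @return Named numeric vector of RMSDs.
#' @export
state_rmsd <- function(state, ctx) {
  vapply(names(ctx$types), function(tp) {
    d <- ctx$types[[tp]]
    sums <- state$sums[[tp]]
    calc <- if (tp == "JC")
      ctx$cfg$jc$mu_A * sums$cos2 / state$n +
        ctx$cfg$jc$mu_B * sums$cos / state$n + ctx$cfg$jc$mu_C
    else .avg_from_sums(tp, sums, state$n)
    rmsd(calc, d$restraints$target)
  }, numeric(1))
}

#' @export
print.ensemble_state <- function(x, ...) {
  cat(sprintf("ensemble_state: N = %d, total objective = %.4f\n", x$n,
              x$total))
  print(signif(x$type_totals, 6))
  invisible(x)
}

#' @export
print.replicate_run <- function(x, ...) {
  cat(sprintf("replicate_run: %d replicate(s), mode = %s, active = %s\n",
              length(x$replicates), x$opt$mode,
              paste(x$active, collapse = "+")))
  cat("optimized scores:\n"); print(x$summary$type_totals)
  cat("optimized RMSDs:\n"); print(x$summary$rmsd)
  if (!is.null(x$composition)) {
    cat("mean pool composition:\n"); print(signif(x$composition, 4))
  }
  invisible(x)
}
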