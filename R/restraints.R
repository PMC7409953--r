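#' Supported experimental data types
#'
#' The eight solution data types the scoring framework understands:
#' chemical shifts (CS, ppm), three-bond J-couplings (JC, Hz), homonuclear
#' NOE distance restraints (NOE, Angstrom), paramagnetic relaxation
#' enhancement distance restraints (PRE, Angstrom), residual dipolar
#' couplings (RDC, Hz), hydrodynamic radius (RH, Angstrom), mean smFRET
#' transfer efficiency (FRET, dimensionless) and SAXS intensities
#' (SAXS, relative intensity on a Q grid in 1/Angstrom).
#'
#' @export
DATATYPES <- c("CS", "JC", "NOE", "PRE", "RDC", "RH", "FRET", "SAXS")

.check_datatype <- function(datatype) {
  datatype <- toupper(datatype)
  if (!datatype %in% DATATYPES)
    stop("unknown datatype '", datatype, "'; must be one of ",
         paste(DATATYPES, collapse = ", "))
  datatype
}

#' Default uncertainty configuration
#'
#' Returns the full set of nuisance-prior constants: per-type back-calculation
#' uncertainties (sigma_q), experimental uncertainties (sigma_ex), the Karplus
#' coefficient priors, the FRET dye model, and the SAXS Shannon-channel
#' parameters. Defaults are the values used for the drkN SH3 unfolded-state
#' study; every field can be overridden via \code{read_config()} or by
#' modifying the returned list.
#'
#' Notes on specific defaults:
#' \itemize{
#'   \item Chemical-shift sigma_q is published as a band (0.3-0.5 ppm for
#'     hydrogens, 1.2-1.4 ppm for carbons); band midpoints are used.
#'   \item NOE/PRE sigma_q = 1e-4 Angstrom: the distance "back-calculation" is
#'     a direct coordinate measurement, so its error is a sentinel near zero.
#'     This makes the offset prior contribute a large constant per restraint,
#'     which dominates absolute NOE/PRE score magnitudes.
#'   \item The FRET sigmas (0.007 back-calculation, 0.02 experimental) are
#'     used on the dimensionless efficiency scale.
#'   \item phi0 = 60 degrees, the standard 3J(HN-HA) Karplus reference for
#'     the Vuister-Bax parameterization.
#' }
#'
#' @return A list of class \code{"uncertainty_config"}.
#' @export
uncertainty_config <- function() {
  cfg <- list(
    cs = list(sigma_ex_h = 0.03, sigma_ex_c = 0.3,
              sigma_q_h = 0.4, sigma_q_c = 1.3),
    jc = list(sigma_ex = 0.5,
              mu_A = 6.51, sigma_A = 0.14,
              mu_B = -1.76, sigma_B = 0.03,
              mu_C = 1.60, sigma_C = 0.08,
              phi0 = 60),
    noe = list(sigma_q = 1e-4, range_divisor = 2),
    pre = list(sigma_q = 1e-4, range_divisor = 4),
    rdc = list(sigma_q = 0.9, sigma_ex = 1.0),
    rh = list(sigma_q = 0.8, sigma_ex = 0.30),
    fret = list(sigma_q = 0.007, sigma_ex = 0.02,
                r0 = 52, n_linker = 9, upsilon = 0.55, n_res = 55),
    saxs = list(sigma_q = 0.006, sigma_ex_lo = 8e-4, sigma_ex_hi = 2e-3,
                d_max = 60, q_min = NA_real_, q_max = NA_real_,
                ns_override = NA_real_, weight_mode = "full")
  )
  class(cfg) <- "uncertainty_config"
  cfg
}

#' Read an uncertainty configuration file
#'
#' Reads a YAML key/value file mirroring the \code{uncertainty_config()}
#' structure (top-level keys \code{cs}, \code{jc}, \code{noe}, \code{pre},
#' \code{rdc}, \code{rh}, \code{fret}, \code{saxs}) and merges it over the
#' defaults, so a config file only needs to state the values it overrides.
#'
#' @param path Path to a YAML file.
#' @return An \code{"uncertainty_config"} list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- uncertainty_config()
  for (key in names(user)) {
    if (!key %in% names(cfg))
      stop("unknown config section '", key, "'")
    bad <- setdiff(names(user[[key]]), names(cfg[[key]]))
    if (length(bad))
      stop("unknown config field(s) in '", key, "': ",
           paste(bad, collapse = ", "))
    cfg[[key]] <- utils::modifyList(cfg[[key]], user[[key]])
  }
  .validate_config(cfg)
  cfg
}

.validate_config <- function(cfg) {
  pos <- c(cfg$cs$sigma_ex_h, cfg$cs$sigma_ex_c, cfg$cs$sigma_q_h,
           cfg$cs$sigma_q_c, cfg$jc$sigma_ex, cfg$jc$sigma_A, cfg$jc$sigma_B,
           cfg$jc$sigma_C, cfg$rdc$sigma_q, cfg$rdc$sigma_ex, cfg$rh$sigma_q,
           cfg$rh$sigma_ex, cfg$fret$sigma_q, cfg$fret$sigma_ex,
           cfg$saxs$sigma_q)
  if (any(pos <= 0)) stop("all sigma values must be > 0")
  if (cfg$noe$sigma_q < 0 || cfg$pre$sigma_q < 0)
    stop("NOE/PRE sigma_q must be >= 0")
  invisible(cfg)
}

# nucleus class of a chemical-shift restraint id of the form "<res>:<atom>";
# atoms starting with H are hydrogens, everything else is carbon-like
.cs_is_hydrogen <- function(id) {
  atom <- sub("^.*:", "", id)
  grepl("^H", atom, ignore.case = TRUE)
}

.default_sigma_ex <- function(datatype, rs, cfg) {
  switch(datatype,
    CS = ifelse(.cs_is_hydrogen(rs$id), cfg$cs$sigma_ex_h, cfg$cs$sigma_ex_c),
    JC = rep(cfg$jc$sigma_ex, nrow(rs)),
    RDC = rep(cfg$rdc$sigma_ex, nrow(rs)),
    RH = rep(cfg$rh$sigma_ex, nrow(rs)),
    FRET = rep(cfg$fret$sigma_ex, nrow(rs)),
    SAXS = {
      q <- as.numeric(rs$id)
      if (length(q) == 1L) rep(cfg$saxs$sigma_ex_hi, 1L)
      else cfg$saxs$sigma_ex_hi +
        (cfg$saxs$sigma_ex_lo - cfg$saxs$sigma_ex_hi) *
          (q - min(q)) / (max(q) - min(q))
    },
    # NOE/PRE sigma_ex comes from the restraint range; no scalar default
    rep(NA_real_, nrow(rs))
  )
}

.default_sigma_q <- function(datatype, rs, cfg) {
  switch(datatype,
    CS = ifelse(.cs_is_hydrogen(rs$id), cfg$cs$sigma_q_h, cfg$cs$sigma_q_c),
    JC = rep(NA_real_, nrow(rs)),  # JC uses the Karplus triple, not an offset
    NOE = rep(cfg$noe$sigma_q, nrow(rs)),
    PRE = rep(cfg$pre$sigma_q, nrow(rs)),
    RDC = rep(cfg$rdc$sigma_q, nrow(rs)),
    RH = rep(cfg$rh$sigma_q, nrow(rs)),
    FRET = rep(cfg$fret$sigma_q, nrow(rs)),
    SAXS = rep(cfg$saxs$sigma_q, nrow(rs))
  )
}

#' Construct a restraint set
#'
#' Builds a validated set of experimental restraints of one data type.
#' Restraint-class ranges, when given, are converted at construction time:
#' the target is the mid-range value and, when \code{sigma_exp} is missing,
#' it is the range width divided by the per-type divisor (2 for NOE, 4 for
#' PRE). Missing \code{sigma_exp} for the other types is filled from the
#' configuration defaults, as is the per-restraint back-calculation
#' uncertainty \code{sigma_q}.
#'
#' @param id Character vector of restraint identifiers (residue+atom for
#'   CS/JC/RDC, atom pair for NOE, tag-site+residue for PRE, the Q value for
#'   SAXS, a singleton label for RH/FRET).
#' @param target Numeric target values (may be NA when \code{lo}/\code{hi}
#'   ranges are given).
#' @param datatype One of \code{DATATYPES}.
#' @param sigma_exp Experimental uncertainty per restraint (NA = fill from
#'   defaults / ranges).
#' @param sigma_q Back-calculation uncertainty per restraint (NA = per-type
#'   default).
#' @param lo,hi Optional restraint-range bounds (Angstrom).
#' @param cfg An \code{uncertainty_config()}.
#' @return A data frame of class \code{"restraint_set"} with columns
#'   \code{id}, \code{target}, \code{sigma_exp}, \code{sigma_q},
#'   \code{range_lo}, \code{range_hi} and attributes \code{datatype},
#'   \code{provenance}.
#' @export
restraint_set <- function(id, target, datatype,
                          sigma_exp = NA_real_, sigma_q = NA_real_,
                          lo = NA_real_, hi = NA_real_,
                          cfg = uncertainty_config()) {
  datatype <- .check_datatype(datatype)
  n <- length(id)
  rs <- data.frame(id = as.character(id),
                   target = rep_len(as.numeric(target), n),
                   sigma_exp = rep_len(as.numeric(sigma_exp), n),
                   sigma_q = rep_len(as.numeric(sigma_q), n),
                   range_lo = rep_len(as.numeric(lo), n),
                   range_hi = rep_len(as.numeric(hi), n),
                   stringsAsFactors = FALSE)
  provenance <- character(0)

  has_range <- !is.na(rs$range_lo) | !is.na(rs$range_hi)
  if (any(has_range)) {
    # a bare upper bound ("<8 A") is an implicit 0-to-hi range
    rs$range_lo[has_range & is.na(rs$range_lo)] <- 0
    if (any(is.na(rs$range_hi[has_range])))
      stop("restraint range with lo but no hi")
    if (any(rs$range_lo[has_range] >= rs$range_hi[has_range]))
      stop("restraint range must satisfy lo < hi")
    mid <- (rs$range_lo + rs$range_hi) / 2
    fill_t <- has_range & is.na(rs$target)
    rs$target[fill_t] <- mid[fill_t]
    if (any(abs(rs$target[has_range] - mid[has_range]) > 1e-9))
      stop("ranged restraints must use the mid-range target convention")
    if (any(fill_t)) provenance <- c(provenance, "target = mid-range")
    div <- switch(datatype, NOE = cfg$noe$range_divisor,
                  PRE = cfg$pre$range_divisor, 2)
    fill_s <- has_range & is.na(rs$sigma_exp)
    rs$sigma_exp[fill_s] <-
      (rs$range_hi[fill_s] - rs$range_lo[fill_s]) / div
    if (any(fill_s))
      provenance <- c(provenance, sprintf("sigma_exp = range/%g", div))
  }

  fill <- is.na(rs$sigma_exp)
  if (any(fill)) {
    def <- .default_sigma_ex(datatype, rs, cfg)
    rs$sigma_exp[fill] <- def[fill]
    if (any(fill)) provenance <- c(provenance, "sigma_exp from defaults")
  }
  fillq <- is.na(rs$sigma_q)
  if (any(fillq)) rs$sigma_q[fillq] <- .default_sigma_q(datatype, rs, cfg)[fillq]

  if (anyNA(rs$target)) stop("missing target value(s)")
  if (anyNA(rs$sigma_exp) || any(rs$sigma_exp <= 0))
    stop("every scored restraint needs sigma_exp > 0")
  if (datatype != "JC" && (anyNA(rs$sigma_q) || any(rs$sigma_q < 0)))
    stop("sigma_q must be >= 0")
  if (anyDuplicated(rs$id)) stop("duplicate restraint id(s)")

  if (datatype == "SAXS") {
    q <- suppressWarnings(as.numeric(rs$id))
    if (anyNA(q)) stop("SAXS restraint ids must be numeric Q values")
    if (is.unsorted(q, strictly = TRUE)) {
      o <- order(q)
      if (anyDuplicated(q)) stop("duplicate SAXS Q values")
      rs <- rs[o, , drop = FALSE]
      rownames(rs) <- NULL
    }
  }

  attr(rs, "datatype") <- datatype
  attr(rs, "provenance") <- unique(provenance)
  class(rs) <- c("restraint_set", "data.frame")
  rs
}

#' Load a restraint table
#'
#' Reads a tab-separated restraint table with a header line; comment lines
#' start with \code{#}. Recognized columns: \code{id}, \code{target},
#' \code{sigma_exp}, \code{sigma_q}, \code{lo}/\code{range_lo},
#' \code{hi}/\code{range_hi}. Only \code{id} is mandatory; ranged restraints
#' may omit \code{target} (mid-range convention) and \code{sigma_exp}
#' (range divided by 2 for NOE, 4 for PRE). Other missing sigmas are filled
#' from \code{cfg}.
#'
#' @param path File path.
#' @param datatype One of \code{DATATYPES}.
#' @param cfg An \code{uncertainty_config()}.
#' @return A \code{restraint_set}.
#' @export
load_restraints <- function(path, datatype, cfg = uncertainty_config()) {
  datatype <- .check_datatype(datatype)
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                      colClasses = NA, stringsAsFactors = FALSE,
                      check.names = FALSE),
    error = function(e) stop("parse error in '", path, "': ",
                             conditionMessage(e)))
  names(tab) <- tolower(names(tab))
  if (!"id" %in% names(tab)) stop("restraint table needs an 'id' column")
  getcol <- function(...) {
    for (nm in c(...)) if (nm %in% names(tab)) return(tab[[nm]])
    NA_real_
  }
  numcol <- function(x, what) {
    if (length(x) == 1L && all(is.na(x))) return(x)
    bad <- which(!is.na(x) & is.na(suppressWarnings(as.numeric(x))))
    if (length(bad))
      stop("malformed ", what, " at data row(s) ",
           paste(bad, collapse = ", "), " of '", path, "'")
    as.numeric(x)
  }
  restraint_set(id = as.character(tab$id),
                target = numcol(getcol("target"), "target"),
                datatype = datatype,
                sigma_exp = numcol(getcol("sigma_exp", "sigma"), "sigma_exp"),
                sigma_q = numcol(getcol("sigma_q"), "sigma_q"),
                lo = numcol(getcol("range_lo", "lo"), "range_lo"),
                hi = numcol(getcol("range_hi", "hi"), "range_hi"),
                cfg = cfg)
}

#' Write a restraint table
#'
#' Writes a \code{restraint_set} back to the tab-separated format read by
#' \code{load_restraints}, at full precision.
#'
#' @param rs A \code{restraint_set}.
#' @param path Output file path.
#' @export
write_restraints <- function(rs, path) {
  stopifnot(inherits(rs, "restraint_set"))
  out <- as.data.frame(rs)
  names(out) <- c("id", "target", "sigma_exp", "sigma_q", "range_lo",
                  "range_hi")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# datatype: ", attr(rs, "datatype")), con)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  out[out == "nan" | out == "NA"] <- ""
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load an experimental SAXS curve
#'
#' Reads a standard 3-column SAXS \code{.dat} file (Q, intensity, sigma;
#' whitespace-separated, optional comment/header lines starting with
#' \code{#}) into a SAXS \code{restraint_set}.
#'
#' @param path File path.
#' @param cfg An \code{uncertainty_config()}.
#' @return A SAXS \code{restraint_set} sorted by increasing Q.
#' @export
load_saxs_curve <- function(path, cfg = uncertainty_config()) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#")
  if (ncol(tab) < 2) stop("SAXS .dat needs at least Q and I columns")
  sigma <- if (ncol(tab) >= 3) as.numeric(tab[[3]]) else NA_real_
  restraint_set(id = format(as.numeric(tab[[1]]), digits = 12),
                target = as.numeric(tab[[2]]), datatype = "SAXS",
                sigma_exp = sigma, cfg = cfg)
}

#' Construct a back-calculation table
#'
#' Pairs a conformer-by-restraint matrix of predicted observables with a
#' \code{restraint_set}. Columns are re-ordered to the restraint order. For
#' JC the stored matrix holds per-conformer cos(phi - phi0); the squared
#' matrix is derived internally, which guarantees the single-conformer
#' identity cos2 = cos^2 cell by cell.
#'
#' @param values Numeric matrix, conformers in rows, columns named by
#'   restraint id (JC: cos(phi - phi0) per conformer per restraint; NOE/PRE:
#'   distances in Angstrom; FRET: per-conformer efficiency; SAXS: I(Q)).
#' @param datatype One of \code{DATATYPES}.
#' @param restraints The paired \code{restraint_set}.
#' @param conformer_ids Optional conformer identifiers (default: rownames or
#'   1..n).
#' @return A list of class \code{"backcalc_table"}.
#' @export
backcalc_table <- function(values, datatype, restraints,
                           conformer_ids = NULL) {
  datatype <- .check_datatype(datatype)
  stopifnot(inherits(restraints, "restraint_set"))
  if (attr(restraints, "datatype") != datatype)
    stop("datatype mismatch between table (", datatype, ") and restraints (",
         attr(restraints, "datatype"), ")")
  values <- as.matrix(values)
  if (ncol(values) > 0L && is.null(colnames(values)))
    stop("back-calculation matrix must have restraint-id column names")
  missing <- setdiff(restraints$id, colnames(values))
  if (length(missing))
    stop("back-calculation table lacks column(s) for restraint(s): ",
         paste(missing, collapse = ", "))
  unknown <- setdiff(colnames(values), restraints$id)
  if (length(unknown))
    stop("back-calculation table has unknown column(s): ",
         paste(unknown, collapse = ", "))
  values <- values[, restraints$id, drop = FALSE]
  if (anyNA(values) || any(!is.finite(values)))
    stop("non-finite cell(s) in back-calculation table")
  if (datatype == "JC" && any(values < -1 | values > 1))
    stop("JC cos terms must lie in [-1, 1]")
  if (datatype %in% c("NOE", "PRE") && any(values <= 0))
    stop("NOE/PRE distances must be > 0")
  if (is.null(conformer_ids))
    conformer_ids <- rownames(values) %||% as.character(seq_len(nrow(values)))
  tab <- list(datatype = datatype,
              conformer_ids = as.character(conformer_ids),
              restraint_ids = restraints$id,
              values = unname(values))
  if (datatype == "JC") tab$cos2 <- tab$values^2
  class(tab) <- "backcalc_table"
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a back-calculation table
#'
#' Reads a tab-separated matrix file: header line, first column the conformer
#' id, remaining columns named by restraint id. Columns may appear in any
#' order; they are aligned to the restraint order, missing or unknown columns
#' are an error, and NaN cells are rejected.
#'
#' @param path File path.
#' @param datatype One of \code{DATATYPES}.
#' @param restraints The paired \code{restraint_set}.
#' @return A \code{backcalc_table}.
#' @export
load_backcalc <- function(path, datatype, restraints) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (ncol(tab) < 2) stop("back-calculation table needs conformer + data columns")
  ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  backcalc_table(m, datatype, restraints, conformer_ids = ids)
}

#' Write a back-calculation table
#'
#' Inverse of \code{load_backcalc}; values are written at full precision so
#' a write/read round trip is bit-identical.
#'
#' @param tab A \code{backcalc_table}.
#' @param path Output file path.
#' @export
write_backcalc <- function(tab, path) {
  stopifnot(inherits(tab, "backcalc_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# datatype: ", tab$datatype), con)
  writeLines(paste(c("conformer", tab$restraint_ids), collapse = "\t"), con)
  body <- apply(tab$values, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(paste(tab$conformer_ids, body, sep = "\t"), con)
  invisible(path)
}

#' @export
`[.restraint_set` <- function(x, i, ...) {
  out <- as.data.frame(x)[i, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "datatype") <- attr(x, "datatype")
  attr(out, "provenance") <- attr(x, "provenance")
  class(out) <- class(x)
  out
}

#' @export
print.restraint_set <- function(x, ...) {
  cat(sprintf("restraint_set: %d %s restraint(s)\n", nrow(x),
              attr(x, "datatype")))
  prov <- attr(x, "provenance")
  if (length(prov)) cat("  provenance:", paste(prov, collapse = "; "), "\n")
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}

#' @export
print.backcalc_table <- function(x, ...) {
  cat(sprintf("backcalc_table: %s, %d conformer(s) x %d restraint(s)\n",
              x$datatype, nrow(x$values), ncol(x$values)))
  invisible(x)
}
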