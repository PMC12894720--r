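# Chronogram data model: interval-censored penetration and fusion time
# windows, one record per spermatozoon, grouped per oocyte.
#
# Times are minutes post-insemination throughout.  A degenerate window
# (lower == upper) encodes a directly observed event time.

#' Create a time window
#'
#' A closed interval `[lower, upper]` of minutes post-insemination bounding
#' one event.  A degenerate window (`lower == upper`) encodes a directly
#' observed event time.
#'
#' @param lower,upper window bounds in minutes post-insemination;
#'   `lower` must be non-negative and at most `upper`.
#' @return a numeric vector `c(lower, upper)` of class `"time_window"`.
#' @examples
#' time_window(30, 75)
#' time_window(30, 30)  # directly observed event
#' @export
time_window <- function(lower, upper) {
  if (!is_scalar_num(lower) || !is_scalar_num(upper))
    stop_fk("time window bounds must be single finite numbers")
  if (lower < 0)
    stop_fk("time window lower bound must be >= 0 (got %g)", lower)
  if (lower > upper)
    stop_fk("invalid time window: lower (%g) > upper (%g)", lower, upper)
  structure(c(lower = unname(lower), upper = unname(upper)),
            class = "time_window")
}

#' @export
print.time_window <- function(x, ...) {
  cat(sprintf("[%g, %g] min\n", x[[1L]], x[[2L]]))
  invisible(x)
}

clip_interval <- function(lower, upper, horizon) {
  c(max(0, min(lower, horizon)), max(0, min(upper, horizon)))
}

empty_sperm_frame <- function() {
  data.frame(oocyte_id = character(), sperm_id = character(),
             pen_lower = numeric(), pen_upper = numeric(),
             fus_lower = numeric(), fus_upper = numeric(),
             fused = logical(), stringsAsFactors = FALSE)
}

oocyte_fate <- function(n_sperm, n_fused) {
  ifelse(n_sperm == 0L, "unpenetrated",
         ifelse(n_fused > 0L, "fertilized", "penetrated_unfertilized"))
}

#' Construct a chronogram
#'
#' A chronogram is the interval-censored event dataset of a kinetic-tracking
#' insemination experiment: for every spermatozoon that penetrated the
#' perivitelline space (PVS) of an observed oocyte, a penetration time window,
#' and, if it fused with the oolemma, a fusion time window.
#'
#' @param sperm data frame with columns `oocyte_id`, `sperm_id`, `pen_lower`,
#'   `pen_upper` and optionally `fus_lower`, `fus_upper` (both `NA` for
#'   non-fused sperm).  May be `NULL` or empty.
#' @param oocytes data frame with columns `oocyte_id` and optionally `horizon`
#'   (observation end, minutes; default 240).  Oocytes absent from `sperm`
#'   are recorded as unpenetrated.  If `NULL`, oocytes are taken from `sperm`.
#' @param condition free-text cohort label (e.g. `"fertilized"`).
#' @param horizon default observation horizon in minutes for oocytes whose
#'   `horizon` is missing.
#' @return an object of class `"chronogram"`: a list with elements `sperm`
#'   (per-sperm table with windows clipped to `[0, horizon]` and a logical
#'   `fused` column), `oocytes` (per-oocyte table with `horizon`, `n_sperm`,
#'   `n_fused`, `fate`) and `condition`.
#' @details Invariants enforced: window bounds satisfy
#'   `0 <= lower <= upper`; a fusion window is present exactly for fused
#'   sperm; `fus_upper >= pen_lower` (fusion cannot certainly precede
#'   penetration); oocyte ids are unique and sperm ids unique within an
#'   oocyte.  Windows are clipped to `[0, horizon]` of their oocyte.
#' @seealso [read_chronogram()], [classify_sperm()], [summary.chronogram()]
#' @export
chronogram <- function(sperm = NULL, oocytes = NULL, condition = "",
                       horizon = 240) {
  if (is.null(sperm) || nrow(sperm) == 0L) sperm <- empty_sperm_frame()
  sperm <- as.data.frame(sperm, stringsAsFactors = FALSE)
  for (col in c("fus_lower", "fus_upper"))
    if (is.null(sperm[[col]])) sperm[[col]] <- rep(NA_real_, nrow(sperm))
  need <- c("oocyte_id", "sperm_id", "pen_lower", "pen_upper")
  miss <- setdiff(need, names(sperm))
  if (length(miss))
    stop_fk("sperm table is missing column(s): %s", paste(miss, collapse = ", "))
  sperm$oocyte_id <- as.character(sperm$oocyte_id)
  sperm$sperm_id <- as.character(sperm$sperm_id)

  if (is.null(oocytes)) {
    oocytes <- data.frame(oocyte_id = unique(sperm$oocyte_id),
                          stringsAsFactors = FALSE)
  }
  oocytes <- as.data.frame(oocytes, stringsAsFactors = FALSE)
  if (is.null(oocytes$oocyte_id))
    stop_fk("oocyte table is missing column: oocyte_id")
  oocytes$oocyte_id <- as.character(oocytes$oocyte_id)
  if (anyDuplicated(oocytes$oocyte_id))
    stop_fk("duplicated oocyte_id: %s",
            paste(unique(oocytes$oocyte_id[duplicated(oocytes$oocyte_id)]),
                  collapse = ", "))
  if (is.null(oocytes$horizon)) oocytes$horizon <- rep(horizon, nrow(oocytes))
  oocytes$horizon[is.na(oocytes$horizon)] <- horizon
  if (any(oocytes$horizon <= 0))
    stop_fk("oocyte horizon must be positive")

  unknown <- setdiff(sperm$oocyte_id, oocytes$oocyte_id)
  if (length(unknown))
    stop_fk("sperm rows reference unknown oocyte_id: %s",
            paste(unknown, collapse = ", "))
  key <- paste(sperm$oocyte_id, sperm$sperm_id, sep = "\r")
  if (anyDuplicated(key))
    stop_fk("duplicated sperm_id within an oocyte: %s",
            paste(unique(sperm$sperm_id[duplicated(key)]), collapse = ", "))

  hz <- oocytes$horizon[match(sperm$oocyte_id, oocytes$oocyte_id)]
  for (i in seq_len(nrow(sperm))) {
    lo <- sperm$pen_lower[i]; up <- sperm$pen_upper[i]
    if (is.na(lo) || is.na(up))
      stop_fk("sperm %s/%s: penetration window bounds must be numeric",
              sperm$oocyte_id[i], sperm$sperm_id[i])
    if (lo < 0 || lo > up)
      stop_fk("sperm %s/%s: invalid penetration window [%g, %g]",
              sperm$oocyte_id[i], sperm$sperm_id[i], lo, up)
    w <- clip_interval(lo, up, hz[i])
    sperm$pen_lower[i] <- w[1L]; sperm$pen_upper[i] <- w[2L]
    flo <- sperm$fus_lower[i]; fup <- sperm$fus_upper[i]
    if (xor(is.na(flo), is.na(fup)))
      stop_fk("sperm %s/%s: fusion window must have both bounds or neither",
              sperm$oocyte_id[i], sperm$sperm_id[i])
    if (!is.na(flo)) {
      if (flo < 0 || flo > fup)
        stop_fk("sperm %s/%s: invalid fusion window [%g, %g]",
                sperm$oocyte_id[i], sperm$sperm_id[i], flo, fup)
      if (fup < sperm$pen_lower[i])
        stop_fk("sperm %s/%s: fusion window ends (%g) before penetration can start (%g)",
                sperm$oocyte_id[i], sperm$sperm_id[i], fup, sperm$pen_lower[i])
      w <- clip_interval(flo, fup, hz[i])
      sperm$fus_lower[i] <- w[1L]; sperm$fus_upper[i] <- w[2L]
    }
  }
  sperm$fused <- !is.na(sperm$fus_lower)

  ns <- as.integer(table(factor(sperm$oocyte_id, levels = oocytes$oocyte_id)))
  nf <- as.integer(table(factor(sperm$oocyte_id[sperm$fused],
                                levels = oocytes$oocyte_id)))
  oocytes$n_sperm <- ns
  oocytes$n_fused <- nf
  oocytes$fate <- oocyte_fate(ns, nf)

  ord <- order(sperm$oocyte_id, sperm$sperm_id, method = "radix")
  sperm <- sperm[ord, c("oocyte_id", "sperm_id", "pen_lower", "pen_upper",
                        "fus_lower", "fus_upper", "fused"), drop = FALSE]
  rownames(sperm) <- NULL
  oocytes <- oocytes[order(oocytes$oocyte_id, method = "radix"),
                     c("oocyte_id", "horizon", "n_sperm", "n_fused", "fate"),
                     drop = FALSE]
  rownames(oocytes) <- NULL

  structure(list(sperm = sperm, oocytes = oocytes,
                 condition = as.character(condition)[1L]),
            class = "chronogram")
}

#' @export
print.chronogram <- function(x, ...) {
  f <- table(factor(x$oocytes$fate,
                    levels = c("fertilized", "penetrated_unfertilized",
                               "unpenetrated")))
  cat(sprintf(paste0(
    "Chronogram%s: %d oocytes (%d fertilized, %d penetrated-unfertilized,",
    " %d unpenetrated), %d sperm (%d fused)\n"),
    if (nzchar(x$condition)) paste0(" [", x$condition, "]") else "",
    nrow(x$oocytes), f[[1L]], f[[2L]], f[[3L]],
    nrow(x$sperm), sum(x$sperm$fused)))
  invisible(x)
}

#' Subset a chronogram by oocyte
#'
#' @param x a [chronogram()].
#' @param oocyte_ids optional character vector of oocyte ids to keep.
#' @param fate optional fate filter: any of `"fertilized"`,
#'   `"penetrated_unfertilized"`, `"unpenetrated"`.
#' @return a chronogram restricted to the selected oocytes.
#' @export
subset_oocytes <- function(x, oocyte_ids = NULL, fate = NULL) {
  stopifnot(inherits(x, "chronogram"))
  keep <- rep(TRUE, nrow(x$oocytes))
  if (!is.null(oocyte_ids)) keep <- keep & x$oocytes$oocyte_id %in% oocyte_ids
  if (!is.null(fate)) keep <- keep & x$oocytes$fate %in% fate
  ids <- x$oocytes$oocyte_id[keep]
  chronogram(x$sperm[x$sperm$oocyte_id %in% ids, , drop = FALSE],
             x$oocytes[keep, c("oocyte_id", "horizon"), drop = FALSE],
             condition = x$condition)
}

# ---------------------------------------------------------------------------
# Table I/O.  One row per sperm; oocytes with no sperm appear as a row with
# empty sperm_id and pen_* fields.  Comma- or tab-delimited, autodetected.

chronogram_columns <- c("oocyte_id", "sperm_id", "pen_lower_min",
                        "pen_upper_min", "fus_lower_min", "fus_upper_min",
                        "horizon_min", "condition")

parse_num_field <- function(x, what, row) {
  if (is.na(x) || x == "") return(NA_real_)
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v))
    stop_fk("row %d: non-numeric %s value '%s'", row, what, x)
  v
}

#' Read a chronogram table
#'
#' Reads a delimited text file (comma or tab, autodetected from the header
#' line) with columns `oocyte_id, sperm_id, pen_lower_min, pen_upper_min,
#' fus_lower_min, fus_upper_min, horizon_min, condition`.  Empty `fus_*`
#' fields mean the sperm did not fuse; a row with empty `sperm_id` and `pen_*`
#' fields records an unpenetrated oocyte.
#'
#' @param path path to the table file.
#' @return a validated [chronogram()].
#' @export
read_chronogram <- function(path) {
  if (!file.exists(path)) stop_fk("file not found: %s", path)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop_fk("empty file: %s", path)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", stringsAsFactors = FALSE,
                           na.strings = NULL, quote = "\"",
                           blank.lines.skip = TRUE)
  miss <- setdiff(chronogram_columns, names(tab))
  if (length(miss))
    stop_fk("chronogram table is missing column(s): %s",
            paste(miss, collapse = ", "))

  sperm <- empty_sperm_frame()
  oo_id <- character(); oo_hz <- numeric()
  condition <- ""
  for (i in seq_len(nrow(tab))) {
    row_no <- i + 1L  # file line, counting the header
    oid <- tab$oocyte_id[i]
    if (is.na(oid) || oid == "")
      stop_fk("row %d: empty oocyte_id", row_no)
    hz <- parse_num_field(tab$horizon_min[i], "horizon_min", row_no)
    if (!(oid %in% oo_id)) {
      oo_id <- c(oo_id, oid)
      oo_hz <- c(oo_hz, hz)
    }
    if (condition == "" && !is.na(tab$condition[i]) && tab$condition[i] != "")
      condition <- tab$condition[i]
    sid <- tab$sperm_id[i]
    if (is.na(sid) || sid == "") next  # unpenetrated oocyte row
    pl <- parse_num_field(tab$pen_lower_min[i], "pen_lower_min", row_no)
    pu <- parse_num_field(tab$pen_upper_min[i], "pen_upper_min", row_no)
    if (is.na(pl) || is.na(pu))
      stop_fk("row %d: missing penetration window bound", row_no)
    if (pl > pu)
      stop_fk("row %d: penetration window lower (%g) > upper (%g)",
              row_no, pl, pu)
    fl <- parse_num_field(tab$fus_lower_min[i], "fus_lower_min", row_no)
    fu <- parse_num_field(tab$fus_upper_min[i], "fus_upper_min", row_no)
    if (xor(is.na(fl), is.na(fu)))
      stop_fk("row %d: fusion window must have both bounds or neither", row_no)
    if (!is.na(fl) && fl > fu)
      stop_fk("row %d: fusion window lower (%g) > upper (%g)", row_no, fl, fu)
    sperm <- rbind(sperm, data.frame(
      oocyte_id = oid, sperm_id = sid, pen_lower = pl, pen_upper = pu,
      fus_lower = fl, fus_upper = fu, fused = !is.na(fl),
      stringsAsFactors = FALSE))
  }
  oocytes <- data.frame(oocyte_id = oo_id, horizon = oo_hz,
                        stringsAsFactors = FALSE)
  chronogram(sperm, oocytes, condition = condition)
}

#' Write a chronogram table
#'
#' Writes the comma-delimited chronogram format read by [read_chronogram()],
#' with deterministic column order and row order (by `oocyte_id` then
#' `sperm_id`), so two writes of the same object are byte-identical.
#'
#' @param x a [chronogram()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_chronogram <- function(x, path) {
  stopifnot(inherits(x, "chronogram"))
  num <- function(v) ifelse(is.na(v), "", formatC(v, format = "g", digits = 15))
  rows <- data.frame(
    oocyte_id = x$sperm$oocyte_id, sperm_id = x$sperm$sperm_id,
    pen_lower_min = num(x$sperm$pen_lower),
    pen_upper_min = num(x$sperm$pen_upper),
    fus_lower_min = num(x$sperm$fus_lower),
    fus_upper_min = num(x$sperm$fus_upper),
    stringsAsFactors = FALSE)
  empty <- x$oocytes$oocyte_id[x$oocytes$n_sperm == 0L]
  if (length(empty))
    rows <- rbind(rows, data.frame(
      oocyte_id = empty, sperm_id = "", pen_lower_min = "",
      pen_upper_min = "", fus_lower_min = "", fus_upper_min = "",
      stringsAsFactors = FALSE))
  rows$horizon_min <-
    num(x$oocytes$horizon[match(rows$oocyte_id, x$oocytes$oocyte_id)])
  rows$condition <- rep(x$condition, nrow(rows))
  rows <- rows[order(rows$oocyte_id, rows$sperm_id, method = "radix"), ,
               drop = FALSE]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(chronogram_columns, collapse = ","), con)
  if (nrow(rows))
    writeLines(do.call(paste, c(unname(as.list(rows)), sep = ",")), con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Sperm categorisation (the chronogram colour code) and cohort summaries.

# first fertilizing sperm = fused sperm with the smallest fusion-window lower
# bound; ties broken by sperm_id order (radix, locale-independent)
first_fertilizing <- function(sdf) {
  fused <- which(sdf$fused)
  if (!length(fused)) return(NA_integer_)
  o <- order(sdf$fus_lower[fused], sdf$sperm_id[fused], method = "radix")
  fused[o[1L]]
}

classify_one <- function(sdf) {
  ref <- first_fertilizing(sdf)
  if (is.na(ref))
    stop_fk("classify_sperm() requires a fertilized oocyte (no fused sperm)")
  cat_ <- rep("ambiguous", nrow(sdf))
  cat_[sdf$fused] <- "fertilizing"
  ref_pen_lower <- sdf$pen_lower[ref]
  ref_fus_upper <- sdf$fus_upper[ref]
  non <- which(!sdf$fused)
  # certain (window-level) ordering only; boundary equality counts as certain
  cat_[non][sdf$pen_upper[non] <= ref_pen_lower] <- "pre_fertilization"
  cat_[non][sdf$pen_lower[non] >= ref_fus_upper] <- "post_fertilization"
  stats::setNames(cat_, sdf$sperm_id)
}

#' Categorise the sperm of a fertilized oocyte
#'
#' Reproduces the chronogram colour code: fused sperm are `fertilizing`
#' (black); a non-fused sperm is `pre_fertilization` (green) if its
#' penetration window certainly precedes the penetration window of the first
#' fertilizing sperm (`pen_upper <=` that sperm's `pen_lower`),
#' `post_fertilization` (purple) if it certainly follows that sperm's fusion
#' window (`pen_lower >=` its `fus_upper`), and `ambiguous` (yellow)
#' otherwise.  The first fertilizing sperm is the fused sperm with the
#' smallest fusion-window lower bound (ties broken by `sperm_id`).
#'
#' @param x a [chronogram()].
#' @param oocyte_id id of a fertilized oocyte; may be omitted when the
#'   chronogram holds a single oocyte.
#' @return named character vector mapping `sperm_id` to category.
#' @export
classify_sperm <- function(x, oocyte_id = NULL) {
  stopifnot(inherits(x, "chronogram"))
  if (is.null(oocyte_id)) {
    if (nrow(x$oocytes) != 1L)
      stop_fk("oocyte_id is required for a multi-oocyte chronogram")
    oocyte_id <- x$oocytes$oocyte_id[1L]
  }
  if (!oocyte_id %in% x$oocytes$oocyte_id)
    stop_fk("unknown oocyte_id: %s", oocyte_id)
  classify_one(x$sperm[x$sperm$oocyte_id == oocyte_id, , drop = FALSE])
}

# outcome of the candidate first penetrant of one fertilized oocyte:
# "fertilized" if the first fertilizing sperm certainly penetrated first,
# "failed" if some other sperm certainly penetrated before it, else
# "ambiguous" (certain ordering = window-level, closed intervals).
first_penetrant_outcome <- function(sdf) {
  ref <- first_fertilizing(sdf)
  others <- setdiff(seq_len(nrow(sdf)), ref)
  if (!length(others)) return("fertilized")
  if (all(sdf$pen_upper[ref] <= sdf$pen_lower[others])) return("fertilized")
  if (any(sdf$pen_upper[others] <= sdf$pen_lower[ref])) return("failed")
  "ambiguous"
}

# penetration timing of each sperm relative to the first fusion window:
# before / after / unknown by certain window ordering
penetration_timing <- function(sdf) {
  ref <- first_fertilizing(sdf)
  timing <- rep("unknown", nrow(sdf))
  timing[sdf$pen_upper <= sdf$fus_lower[ref]] <- "before"
  timing[sdf$pen_lower >= sdf$fus_upper[ref]] <- "after"
  timing[ref] <- "before"  # the fertilizing sperm penetrated before it fused
  timing
}

#' Summarise a chronogram
#'
#' @param object a [chronogram()].
#' @param ... unused.
#' @return an object of class `"chronogram_summary"`: a list with
#'   \describe{
#'     \item{fate_counts}{oocytes per fate.}
#'     \item{penetrations_per_oocyte}{table of sperm counts per oocyte.}
#'     \item{first_penetrant}{among fertilized oocytes, fractions of candidate
#'       first penetrants that certainly fertilized / certainly failed /
#'       remain ambiguous (sums to 1).}
#'     \item{timing_groups}{sperm of fertilized oocytes grouped by certain
#'       penetration timing relative to the first fusion window
#'       (before / after / unknown), with the fused fraction in each group.}
#'     \item{dispermic}{number of oocytes with two or more fused sperm.}
#'   }
#' @export
summary.chronogram <- function(object, ...) {
  x <- object
  fates <- table(factor(x$oocytes$fate,
                        levels = c("fertilized", "penetrated_unfertilized",
                                   "unpenetrated")))
  pen_dist <- table(x$oocytes$n_sperm)
  fert_ids <- x$oocytes$oocyte_id[x$oocytes$fate == "fertilized"]

  fp <- c(fertilized = 0L, failed = 0L, ambiguous = 0L)
  tg <- data.frame(timing = c("before", "after", "unknown"),
                   n = 0L, n_fused = 0L, fused_fraction = NA_real_,
                   stringsAsFactors = FALSE)
  for (oid in fert_ids) {
    sdf <- x$sperm[x$sperm$oocyte_id == oid, , drop = FALSE]
    out <- first_penetrant_outcome(sdf)
    fp[[out]] <- fp[[out]] + 1L
    tim <- penetration_timing(sdf)
    for (g in tg$timing) {
      sel <- tim == g
      tg$n[tg$timing == g] <- tg$n[tg$timing == g] + sum(sel)
      tg$n_fused[tg$timing == g] <-
        tg$n_fused[tg$timing == g] + sum(sdf$fused[sel])
    }
  }
  tg$fused_fraction <- ifelse(tg$n > 0, tg$n_fused / tg$n, NA_real_)
  structure(list(
    condition = x$condition,
    n_oocytes = nrow(x$oocytes),
    fate_counts = fates,
    penetrations_per_oocyte = pen_dist,
    first_penetrant = if (length(fert_ids)) fp / length(fert_ids) else
      fp * NA_real_,
    first_penetrant_n = length(fert_ids),
    timing_groups = tg,
    dispermic = sum(x$oocytes$n_fused >= 2L)
  ), class = "chronogram_summary")
}

#' @export
print.chronogram_summary <- function(x, ...) {
  cat(sprintf("Chronogram summary%s (%d oocytes)\n",
              if (nzchar(x$condition)) paste0(" [", x$condition, "]") else "",
              x$n_oocytes))
  cat("Oocyte fates:\n")
  print(x$fate_counts)
  cat("Penetrated sperm per oocyte:\n")
  print(x$penetrations_per_oocyte)
  if (x$first_penetrant_n) {
    cat(sprintf(
      "First penetrant outcome (n=%d fertilized oocytes): %.1f%% fertilized, %.1f%% failed, %.1f%% ambiguous\n",
      x$first_penetrant_n, 100 * x$first_penetrant[["fertilized"]],
      100 * x$first_penetrant[["failed"]],
      100 * x$first_penetrant[["ambiguous"]]))
    tg <- x$timing_groups
    for (i in seq_len(nrow(tg)))
      cat(sprintf("  penetrated %s first fusion: %d sperm, %s fused\n",
                  tg$timing[i], tg$n[i],
                  if (tg$n[i]) sprintf("%.1f%%", 100 * tg$fused_fraction[i])
                  else "-"))
    cat(sprintf("Dispermic oocytes: %d\n", x$dispermic))
  }
  invisible(x)
}
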