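# Data schema, validation, GFP-penetrance filtering and replicate aggregation.
#
# A dataset is three long-format tables keyed by replicate_id:
#   groups:     one row per focal x mating group (mating counts),
#   recipients: one row per sperm recipient (sperm and offspring counts),
#   penetrance: one row per focal (GFP-marker screen).

GROUP_COLS <- c("replicate_id", "batch", "group_label",
                "total_matings", "focal_matings")
RECIPIENT_COLS <- c("replicate_id", "group_label", "recipient_index",
                    "total_sperm", "focal_sperm", "egg_in_antrum",
                    "total_offspring", "focal_offspring")
PENETRANCE_COLS <- c("replicate_id", "offspring_screened", "gfp_positive")

#' Assemble and validate a mating-group dataset
#'
#' Bundles the three observation tables of the sequential mating-group design
#' into a single validated object. Each focal worm (a *replicate*) is exposed
#' to successive groups of four partners; per group we record the dyadic
#' copulation counts, and per partner (recipient) the stored-sperm and
#' offspring counts with the focal's share identified by a dominant GFP
#' marker. Recipients whose antrum holds an egg have an unobservable total
#' sperm count (encoded as `NA` with `egg_in_antrum = TRUE`).
#'
#' @param groups data.frame with columns `replicate_id`, `batch`,
#'   `group_label`, `total_matings`, `focal_matings`.
#' @param recipients data.frame with columns `replicate_id`, `group_label`,
#'   `recipient_index`, `total_sperm` (`NA` allowed), `focal_sperm`,
#'   `egg_in_antrum`, `total_offspring`, `focal_offspring`.
#' @param penetrance optional data.frame with columns `replicate_id`,
#'   `offspring_screened`, `gfp_positive`.
#' @param validate run invariant checks (default `TRUE`).
#' @return an object of class `repsel_data` (a list of the three tables).
#' @export
repsel_data <- function(groups, recipients, penetrance = NULL,
                        validate = TRUE) {
  groups <- as.data.frame(groups)
  recipients <- as.data.frame(recipients)
  if (!is.null(penetrance)) penetrance <- as.data.frame(penetrance)
  x <- structure(list(groups = groups, recipients = recipients,
                      penetrance = penetrance),
                 class = "repsel_data")
  if (validate) validate_observations(x)
  x
}

#' @export
print.repsel_data <- function(x, ...) {
  cat("repsel_data:",
      length(unique(x$groups$replicate_id)), "replicates,",
      nrow(x$groups), "group observations,",
      nrow(x$recipients), "recipient observations\n")
  if (!is.null(x$penetrance))
    cat("  penetrance records:", nrow(x$penetrance), "\n")
  invisible(x)
}

schema_check <- function(df, required, table) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("schema error in '%s' table: missing column(s) %s",
                 table, paste(missing, collapse = ", ")), call. = FALSE)
}

#' Validate a dataset against the schema invariants
#'
#' Checks every row-level invariant (focal counts never exceed totals, counts
#' nonnegative integers, missing total sperm only with the egg flag set,
#' recipients matched to a group row) and raises a single error listing all
#' offending rows.
#'
#' @param x a `repsel_data` object.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_observations <- function(x) {
  g <- x$groups; r <- x$recipients; p <- x$penetrance
  schema_check(g, GROUP_COLS, "groups")
  schema_check(r, RECIPIENT_COLS, "recipients")
  if (!is.null(p)) schema_check(p, PENETRANCE_COLS, "penetrance")

  probs <- character(0)
  bad <- function(tbl, rows, msg) {
    if (any(rows)) sprintf("%s row(s) %s: %s", tbl,
                           paste(which(rows), collapse = ","), msg)
  }
  probs <- c(probs,
    bad("groups", !is_count(g$total_matings) | !is_count(g$focal_matings),
        "mating counts must be nonnegative integers"),
    bad("groups", is_count(g$total_matings) & is_count(g$focal_matings) &
          g$focal_matings > g$total_matings,
        "focal_matings > total_matings"),
    bad("groups", !is_count(g$batch), "batch must be a positive integer"),
    bad("recipients", !is_count(r$focal_sperm) |
          !is_count(r$total_offspring) | !is_count(r$focal_offspring),
        "counts must be nonnegative integers"),
    bad("recipients", !is.na(r$total_sperm) & !is_count(r$total_sperm),
        "total_sperm must be a nonnegative integer or missing"),
    bad("recipients", !is.na(r$total_sperm) & is_count(r$total_sperm) &
          is_count(r$focal_sperm) & r$focal_sperm > r$total_sperm,
        "focal_sperm > total_sperm"),
    bad("recipients", is_count(r$total_offspring) &
          is_count(r$focal_offspring) &
          r$focal_offspring > r$total_offspring,
        "focal_offspring > total_offspring"),
    bad("recipients", is.na(r$total_sperm) & !r$egg_in_antrum,
        "total_sperm missing without egg_in_antrum"),
    bad("recipients",
        !paste(r$replicate_id, r$group_label) %in%
          paste(g$replicate_id, g$group_label),
        "no matching group observation"))
  if (!is.null(p)) {
    probs <- c(probs,
      bad("penetrance", !is_count(p$offspring_screened) |
            !is_count(p$gfp_positive),
          "screen counts must be nonnegative integers"),
      bad("penetrance", is_count(p$offspring_screened) &
            is_count(p$gfp_positive) &
            p$gfp_positive > p$offspring_screened,
          "gfp_positive > offspring_screened"))
  }
  dup <- duplicated(g[c("replicate_id", "group_label")])
  probs <- c(probs, bad("groups", dup, "duplicated replicate x group"))
  probs <- Filter(Negate(is.null), probs)
  if (length(probs))
    stop("validation error:\n  ", paste(unlist(probs), collapse = "\n  "),
         call. = FALSE)
  invisible(x)
}

#' Read observation tables from disk
#'
#' Reads the three CSV/TSV tables of a dataset directory (or explicitly named
#' files) and returns a validated [repsel_data]. Missing total sperm counts
#' are encoded as empty fields. A `schema` mapping renames nonstandard column
#' headers to the canonical names, per table.
#'
#' @param path directory containing `groups.csv`, `recipients.csv` and
#'   (optionally) `penetrance.csv`, or a named character vector / list with
#'   entries `groups`, `recipients`, `penetrance`.
#' @param schema optional named list of named character vectors, e.g.
#'   `list(groups = c(total_matings = "tot_cop"))`, mapping canonical names to
#'   file column names.
#' @param sep field separator, `","` by default (use `"\t"` for TSV).
#' @return a validated `repsel_data` object.
#' @export
read_observations <- function(path, schema = NULL, sep = ",") {
  if (length(path) == 1L && dir.exists(path)) {
    files <- list(groups = file.path(path, "groups.csv"),
                  recipients = file.path(path, "recipients.csv"),
                  penetrance = file.path(path, "penetrance.csv"))
    if (!file.exists(files$penetrance)) files$penetrance <- NULL
  } else {
    files <- as.list(path)
  }
  for (nm in c("groups", "recipients")) {
    if (is.null(files[[nm]]) || !file.exists(files[[nm]]))
      stop(sprintf("file for '%s' table not found", nm), call. = FALSE)
  }
  read_one <- function(f, map, required) {
    df <- utils::read.csv(f, sep = sep, stringsAsFactors = FALSE)
    if (!is.null(map)) {
      for (canon in names(map)) {
        if (!map[[canon]] %in% names(df))
          stop(sprintf("schema error: column '%s' (mapped to '%s') absent in %s",
                       map[[canon]], canon, f), call. = FALSE)
        names(df)[names(df) == map[[canon]]] <- canon
      }
    }
    schema_check(df, required, basename(f))
    df
  }
  g <- read_one(files$groups, schema$groups, GROUP_COLS)
  r <- read_one(files$recipients, schema$recipients, RECIPIENT_COLS)
  r$egg_in_antrum <- as.logical(r$egg_in_antrum)
  p <- if (!is.null(files$penetrance))
    read_one(files$penetrance, schema$penetrance, PENETRANCE_COLS)
  repsel_data(g, r, p)
}

#' Write a dataset to disk
#'
#' Inverse of [read_observations()]: writes `groups.csv`, `recipients.csv`
#' and, if present, `penetrance.csv` under `dir`. Missing totals become empty
#' fields.
#'
#' @param x a `repsel_data` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_observations <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(x$groups[GROUP_COLS], file.path(dir, "groups.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(x$recipients[RECIPIENT_COLS],
                   file.path(dir, "recipients.csv"), row.names = FALSE,
                   na = "")
  if (!is.null(x$penetrance))
    utils::write.csv(x$penetrance[PENETRANCE_COLS],
                     file.path(dir, "penetrance.csv"), row.names = FALSE,
                     na = "")
  invisible(dir)
}

#' Exclude focals with unreliable GFP paternity marker
#'
#' Focal offspring are identified by a dominant GFP transgene; a focal whose
#' marker is incompletely penetrant under-reports its paternity. This filter
#' drops every observation of focals whose screen shows fewer than
#' `min_fraction` GFP-positive offspring, and (optionally) focals that
#' produced no screenable offspring at all. No per-offspring correction is
#' applied to retained focals.
#'
#' @param x a `repsel_data` object with a penetrance table.
#' @param min_fraction minimum GFP-positive fraction to retain a focal
#'   (default 0.90).
#' @param require_offspring drop focals with `offspring_screened == 0`
#'   (default `TRUE`).
#' @return the filtered `repsel_data`; attribute `"exclusions"` holds a
#'   data.frame listing each flagged focal and the reason
#'   (`low_penetrance`, `no_screen_offspring`, `no_penetrance_record` --
#'   the last is flagged but not excluded).
#' @export
apply_penetrance_filter <- function(x, min_fraction = 0.90,
                                    require_offspring = TRUE) {
  if (is.null(x$penetrance))
    stop("dataset has no penetrance table", call. = FALSE)
  p <- x$penetrance
  ids <- unique(x$groups$replicate_id)

  frac <- ifelse(p$offspring_screened > 0,
                 p$gfp_positive / p$offspring_screened, NA_real_)
  excl <- data.frame(replicate_id = character(0), reason = character(0),
                     offspring_screened = numeric(0), fraction = numeric(0),
                     excluded = logical(0), stringsAsFactors = FALSE)
  add <- function(id, reason, screened, fr, excluded) {
    rbind(excl, data.frame(replicate_id = id, reason = reason,
                           offspring_screened = screened, fraction = fr,
                           excluded = excluded, stringsAsFactors = FALSE))
  }
  no_rec <- setdiff(ids, p$replicate_id)
  for (id in no_rec) excl <- add(id, "no_penetrance_record", NA, NA, FALSE)
  if (require_offspring) {
    zero <- p$replicate_id[p$offspring_screened == 0]
    for (id in intersect(zero, ids))
      excl <- add(id, "no_screen_offspring", 0, NA, TRUE)
  }
  low <- p$replicate_id[!is.na(frac) & frac < min_fraction]
  for (id in intersect(low, ids))
    excl <- add(id, "low_penetrance",
                p$offspring_screened[p$replicate_id == id][1],
                frac[p$replicate_id == id][1], TRUE)

  drop <- unique(excl$replicate_id[excl$excluded])
  out <- repsel_data(
    x$groups[!x$groups$replicate_id %in% drop, , drop = FALSE],
    x$recipients[!x$recipients$replicate_id %in% drop, , drop = FALSE],
    x$penetrance, validate = FALSE)
  attr(out, "exclusions") <- excl
  out
}

#' Sum counts across mating groups within each replicate
#'
#' Pools the three (or fewer, when a recording failed) mating groups of each
#' focal into one row of summed counts: matings (`m_t`, `m_f`), stored sperm
#' (`s_t`, `s_f`) and offspring (`o_t`, `o_f`). Total sperm must already be
#' imputed (see [impute_total_sperm()]) if any egg-bearing recipient lacks an
#' observed total.
#'
#' @param x a `repsel_data` object.
#' @return data.frame with one row per replicate: `replicate_id`, `batch`,
#'   `m_t`, `m_f`, `s_t`, `s_f`, `o_t`, `o_f`, `n_groups`, `groups_present`
#'   (comma-separated labels).
#' @export
aggregate_replicates <- function(x) {
  if (anyNA(x$recipients$total_sperm))
    stop("total_sperm contains missing values; run impute_total_sperm() first",
         call. = FALSE)
  g <- x$groups; r <- x$recipients
  if (!nrow(g)) stop("no group observations to aggregate", call. = FALSE)
  ids <- unique(g$replicate_id)
  f <- factor(g$replicate_id, levels = ids)
  fr <- factor(r$replicate_id, levels = ids)
  agg <- data.frame(
    replicate_id = ids,
    batch = as.vector(tapply(g$batch, f, function(b) b[1])),
    m_t = as.vector(tapply(g$total_matings, f, sum)),
    m_f = as.vector(tapply(g$focal_matings, f, sum)),
    s_t = as.vector(tapply(r$total_sperm, fr, sum)),
    s_f = as.vector(tapply(r$focal_sperm, fr, sum)),
    o_t = as.vector(tapply(r$total_offspring, fr, sum)),
    o_f = as.vector(tapply(r$focal_offspring, fr, sum)),
    n_groups = as.vector(tapply(g$group_label, f, length)),
    groups_present = as.vector(tapply(g$group_label, f,
                                      function(l) paste(sort(l), collapse = ","))),
    stringsAsFactors = FALSE)
  for (col in c("s_t", "s_f", "o_t", "o_f"))
    agg[[col]][is.na(agg[[col]])] <- 0L
  agg
}
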