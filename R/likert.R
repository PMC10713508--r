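#' The SHSQ-25 item catalogue
#'
#' The 25 items of the Suboptimal Health Status Questionnaire grouped into
#' its five health domains: cardiovascular system (CS, 3 items), digestive
#' system (DS, 3), fatigue (FT, 9), immune system (IS, 3) and mental health
#' (MH, 7). Each item is rated 0 ("never or almost never") to 4 ("always").
#'
#' @return A data frame with columns `item` and `domain`, one row per item,
#'   in canonical order (CS1..CS3, DS1..DS3, FT1..FT9, IS1..IS3, MH1..MH7).
#' @export
#' @examples
#' table(shsq25_items()$domain)
shsq25_items <- function() {
  p <- .load_presets()
  data.frame(item = p$items, domain = p$domains, stringsAsFactors = FALSE)
}

.load_presets <- function() {
  if (is.null(.shsnet_env$presets)) {
    path <- system.file("extdata", "shsq25_presets.json", package = "shsnet")
    .shsnet_env$presets <- jsonlite::read_json(path, simplifyVector = TRUE)
  }
  .shsnet_env$presets
}

.shsnet_env <- new.env(parent = emptyenv())

#' Construct a validated Likert response matrix
#'
#' The raw analysis input: a respondents-by-items matrix of integer ratings
#' on the 0--4 scale, an item-to-domain map, and optional per-respondent
#' covariates. Ratings outside \{0, ..., 4\} or non-integer ratings are
#' rejected with the offending cells named; missing entries are kept as `NA`
#' and flagged, never imputed.
#'
#' @param ratings Numeric matrix or data frame, one row per respondent,
#'   columns named by item code.
#' @param domain_map Named character vector mapping item code to domain.
#'   Defaults to the canonical SHSQ-25 map when the columns are the 25
#'   canonical items.
#' @param respondent_ids Optional identifiers (default: row index).
#' @param covariates Optional data frame of per-respondent covariates.
#' @return An object of class `likert_matrix`.
#' @export
likert_matrix <- function(ratings, domain_map = NULL, respondent_ids = NULL,
                          covariates = NULL) {
  ratings <- as.matrix(ratings)
  if (is.null(colnames(ratings)))
    stop("ratings must have item codes as column names", call. = FALSE)
  storage <- suppressWarnings(as.numeric(ratings))
  dim(storage) <- dim(ratings)
  dimnames(storage) <- dimnames(ratings)
  ratings <- storage

  bad_num <- which(!is.na(ratings) & (ratings != round(ratings)), arr.ind = TRUE)
  if (nrow(bad_num) > 0)
    stop("non-integer rating(s) at ",
         .cell_labels(bad_num, ratings), call. = FALSE)
  bad_rng <- which(!is.na(ratings) & (ratings < 0 | ratings > 4),
                   arr.ind = TRUE)
  if (nrow(bad_rng) > 0)
    stop("rating(s) outside 0..4 at ",
         .cell_labels(bad_rng, ratings), call. = FALSE)

  items <- colnames(ratings)
  if (is.null(domain_map)) {
    cat25 <- shsq25_items()
    if (all(items %in% cat25$item)) {
      domain_map <- stats::setNames(cat25$domain, cat25$item)[items]
    } else {
      domain_map <- stats::setNames(rep("ALL", length(items)), items)
    }
  }
  if (!all(items %in% names(domain_map)))
    stop("domain_map misses item(s): ",
         paste(setdiff(items, names(domain_map)), collapse = ", "),
         call. = FALSE)
  domain_map <- domain_map[items]

  if (is.null(respondent_ids)) respondent_ids <- as.character(seq_len(nrow(ratings)))
  if (length(respondent_ids) != nrow(ratings))
    stop("respondent_ids length mismatch", call. = FALSE)
  rownames(ratings) <- respondent_ids
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != nrow(ratings))
      stop("covariates must have one row per respondent", call. = FALSE)
  }
  structure(list(ratings = ratings, domain_map = domain_map,
                 respondent_ids = respondent_ids, covariates = covariates,
                 n_missing = sum(is.na(ratings))),
            class = "likert_matrix")
}

.cell_labels <- function(idx, m) {
  lab <- apply(idx, 1, function(rc)
    sprintf("[row %s, item %s] = %s", rownames(m)[rc[1]] %||% rc[1],
            colnames(m)[rc[2]], format(m[rc[1], rc[2]])))
  paste(utils::head(lab, 10), collapse = "; ")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read respondent-level Likert data from CSV
#'
#' Expects UTF-8 CSV with a header row and one respondent per row; item
#' columns named by item code. Columns not listed as items become covariates.
#'
#' @param path CSV file path.
#' @param items Item codes expected in the file (default the SHSQ-25 set).
#' @param id_column Optional name of an identifier column.
#' @return A [likert_matrix()].
#' @export
read_likert_csv <- function(path, items = shsq25_items()$item,
                            id_column = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing_items <- setdiff(items, names(df))
  if (length(missing_items) > 0)
    stop("missing item column(s): ", paste(missing_items, collapse = ", "),
         call. = FALSE)
  ids <- if (!is.null(id_column)) as.character(df[[id_column]]) else NULL
  covar_cols <- setdiff(names(df), c(items, id_column))
  covariates <- if (length(covar_cols) > 0) df[covar_cols] else NULL
  likert_matrix(df[items], respondent_ids = ids, covariates = covariates)
}

#' Write a Likert response matrix as CSV
#'
#' Round-trips through [read_likert_csv()]: item columns in catalogue order,
#' covariate columns appended.
#'
#' @param m A [likert_matrix()].
#' @param path Output file path.
#' @export
write_likert_csv <- function(m, path) {
  stopifnot(inherits(m, "likert_matrix"))
  df <- as.data.frame(m$ratings)
  if (!is.null(m$covariates)) df <- cbind(df, m$covariates)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.likert_matrix <- function(x, ...) {
  cat(sprintf("Likert response matrix: %d respondents x %d items (%s)\n",
              nrow(x$ratings), ncol(x$ratings),
              paste(sprintf("%s:%d", names(table(x$domain_map)),
                            as.integer(table(x$domain_map))), collapse = " ")))
  if (x$n_missing > 0)
    cat(sprintf("  %d missing rating(s) flagged\n", x$n_missing))
  if (!is.null(x$covariates))
    cat("  covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.likert_matrix <- function(x) dim(x$ratings)
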