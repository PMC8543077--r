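#' The harmonised 11-item socio-emotional scale
#'
#' Metadata for the short behaviour scale shared by the two cohort studies:
#' six externalising (EXT) and five internalising (INT) items, eight of them
#' coded in three ordered categories and three binary ("applies"/"does not
#' apply"). Each item loads on exactly one factor (a congeneric structure).
#' Items describe problem behaviours, so raw codes run from "does not apply"
#' to "certainly applies"; analysis codes are reversed where necessary so that
#' higher always means better behaviour.
#'
#' @return A data frame with columns `item_id`, `title`, `factor`
#'   (`"EXT"`/`"INT"`), `n_categories` (2 or 3) and `positively_worded`
#'   (logical; `TRUE` means the raw coding already runs low = worse, so no
#'   reversal is applied).
#' @export
#' @examples
#' socioemotional_items()
socioemotional_items <- function() {
  meta <- data.frame(
    item_id = 1:11,
    title = c("Restless", "Squirmy/fidgety", "Fights/bullies", "Distracted",
              "Tantrums", "Disobedient",
              "Worried", "Fearful", "Solitary", "Unhappy", "Aches"),
    factor = c(rep("EXT", 6), rep("INT", 5)),
    n_categories = c(3L, 3L, 3L, 3L, 2L, 2L, 3L, 3L, 3L, 3L, 2L),
    positively_worded = FALSE,
    stringsAsFactors = FALSE
  )
  validate_item_meta(meta)
  meta
}

validate_item_meta <- function(meta) {
  stopifnot(is.data.frame(meta),
            all(c("item_id", "factor", "n_categories", "positively_worded")
                %in% names(meta)))
  if (anyDuplicated(meta$item_id)) stop("duplicate item_id in item metadata")
  if (!all(meta$factor %in% c("EXT", "INT")))
    stop("item factor must be 'EXT' or 'INT'")
  if (!all(meta$n_categories %in% 2:3))
    stop("items must have 2 or 3 categories")
  invisible(meta)
}

item_cols <- function(meta) paste0("item_", meta$item_id)

#' Build the per-item recode map implied by item wording
#'
#' Negatively worded items (problem behaviours) are reversed so that the
#' highest analysis code is the best behaviour; positively worded items keep
#' their raw order. Codes are 0-based consecutive integers.
#'
#' @param meta item metadata (see [socioemotional_items()]).
#' @return Named list, one integer vector per item: `map[raw + 1] = recoded`.
#' @export
default_recode_map <- function(meta = socioemotional_items()) {
  out <- lapply(seq_len(nrow(meta)), function(i) {
    K <- meta$n_categories[i]
    raw <- 0:(K - 1)
    rec <- if (meta$positively_worded[i]) raw else (K - 1L) - raw
    rec <- as.integer(rec)
    names(rec) <- raw
    rec
  })
  names(out) <- meta$item_id
  out
}

#' Invert a recode map
#'
#' Recoding is a bijection per item; this returns the inverse map so raw codes
#' can be restored exactly.
#' @param recode_map as returned by [default_recode_map()].
#' @return Named list of inverse maps.
#' @export
invert_recode_map <- function(recode_map) {
  lapply(recode_map, function(m) {
    inv <- as.integer(names(m))
    names(inv) <- m
    inv[order(as.integer(names(inv)))]
  })
}

#' Load an ordinal item panel from CSV
#'
#' Reads one row per child, recodes item responses so higher = better
#' behaviour, enforces the complete-case rule on item responses, and records
#' how many rows were dropped. Covariate or outcome columns are carried along
#' untouched.
#'
#' @param path CSV file with a header; must contain `child_id`, `group` and
#'   one `item_<id>` column per item in `meta`.
#' @param meta item metadata data frame.
#' @param recode_map per-item raw-to-analysis code maps; defaults to the map
#'   implied by item wording.
#' @param groups optional character vector of valid group labels; any other
#'   label is an error.
#' @return An object of class `item_panel`: a list with `data` (recoded
#'   responses + extra columns), `meta`, `groups`, `dropped_n`, and
#'   `recode_map`.
#' @export
load_panel <- function(path, meta = socioemotional_items(),
                       recode_map = default_recode_map(meta),
                       groups = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_item_panel(raw, meta = meta, recode_map = recode_map, groups = groups)
}

#' Construct an item panel from an in-memory data frame
#'
#' Same contract as [load_panel()] but starting from a data frame (the form
#' the synthetic generator produces). Set `recode_map = NULL` when responses
#' are already on the analysis coding.
#' @inheritParams load_panel
#' @param data data frame with `child_id`, `group`, and `item_<id>` columns.
#' @export
as_item_panel <- function(data, meta = socioemotional_items(),
                          recode_map = NULL, groups = NULL) {
  validate_item_meta(meta)
  cols <- item_cols(meta)
  missing_cols <- setdiff(c("child_id", "group", cols), names(data))
  if (length(missing_cols))
    stop("panel is missing columns: ", paste(missing_cols, collapse = ", "))

  if (!is.null(groups)) {
    bad <- setdiff(unique(data$group), groups)
    if (length(bad))
      stop("unknown group label(s): ", paste(bad, collapse = ", "))
  } else {
    groups <- unique(as.character(data$group))
  }

  # recode, checking every observed raw category is covered
  if (!is.null(recode_map)) {
    for (i in seq_len(nrow(meta))) {
      id <- as.character(meta$item_id[i])
      cl <- cols[i]
      m <- recode_map[[id]]
      if (is.null(m)) stop("recode_map has no entry for item ", id)
      x <- data[[cl]]
      obs <- unique(x[!is.na(x)])
      bad <- setdiff(as.character(obs), names(m))
      if (length(bad))
        stop("unknown raw category for item ", id, ": ",
             paste(bad, collapse = ", "))
      data[[cl]] <- unname(m[as.character(x)])
    }
  }

  # range check on analysis codes
  for (i in seq_len(nrow(meta))) {
    x <- data[[cols[i]]]
    ok <- is.na(x) | (x >= 0 & x < meta$n_categories[i])
    if (!all(ok))
      stop("item ", meta$item_id[i], " has codes outside 0..",
           meta$n_categories[i] - 1)
  }

  complete <- stats::complete.cases(data[cols])
  dropped <- sum(!complete)
  data <- data[complete, , drop = FALSE]
  rownames(data) <- NULL

  structure(list(data = data, meta = meta, groups = groups,
                 dropped_n = dropped, recode_map = recode_map),
            class = "item_panel")
}

#' @export
print.item_panel <- function(x, ...) {
  cat("<item_panel> ", nrow(x$data), " children, ",
      nrow(x$meta), " items, groups: ",
      paste(x$groups, collapse = ", "), "\n", sep = "")
  if (x$dropped_n > 0)
    cat("  (", x$dropped_n, " rows dropped for incomplete item responses)\n",
        sep = "")
  invisible(x)
}

#' Per-group, per-item category prevalence
#'
#' @param panel an `item_panel`.
#' @return Tidy data frame with columns `group`, `item_id`, `category`,
#'   `proportion`, `n` (group size); proportions sum to 1 within each
#'   item-by-group cell.
#' @export
prevalence_table <- function(panel) {
  stopifnot(inherits(panel, "item_panel"))
  if (nrow(panel$data) == 0) stop("empty panel")
  cols <- item_cols(panel$meta)
  out <- list()
  for (g in panel$groups) {
    sub <- panel$data[panel$data$group == g, , drop = FALSE]
    if (nrow(sub) == 0) stop("empty group: ", g)
    for (i in seq_len(nrow(panel$meta))) {
      K <- panel$meta$n_categories[i]
      counts <- tabulate(sub[[cols[i]]] + 1L, nbins = K)
      out[[length(out) + 1L]] <- data.frame(
        group = g, item_id = panel$meta$item_id[i], category = 0:(K - 1),
        proportion = counts / nrow(sub), n = nrow(sub))
    }
  }
  do.call(rbind, out)
}
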