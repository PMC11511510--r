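#' Write a trial dataset to CSV
#'
#' Writes either the long dialect (columns `accession`, `year`, `block`,
#' `column`, `trait`, `value`) or the wide dialect (one column per trait).
#' If the dataset carries a `truth` attribute (generating parameters from
#' [generate_trial()]), a JSON sidecar `<path>.truth.json` records it.
#'
#' @param data A `trial_data` data frame.
#' @param path Output CSV path.
#' @param dialect `"long"` (default) or `"wide"`.
#' @param truth Optional generating-parameter list overriding the `truth`
#'   attribute.
#' @return `path`, invisibly.
#' @export
write_trial <- function(data, path, dialect = c("long", "wide"),
                        truth = attr(data, "truth")) {
  dialect <- match.arg(dialect)
  out <- if (dialect == "long") {
    data.frame(lapply(data[c("accession", "year", "block", "column",
                             "trait", "value")], as.character),
               stringsAsFactors = FALSE)
  } else {
    trial_to_wide(data)
  }
  if (dialect == "long") out$value <- data$value
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  if (!is.null(truth)) {
    jsonlite::write_json(truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

trial_to_wide <- function(data) {
  keys <- unique(data[c("accession", "year", "block", "column")])
  keys <- data.frame(lapply(keys, as.character), stringsAsFactors = FALSE)
  traits <- as.character(unique(data$trait))
  id_d <- paste(as.character(data$accession), as.character(data$year),
                as.character(data$block), as.character(data$column))
  id_k <- paste(keys$accession, keys$year, keys$block, keys$column)
  for (tn in traits) {
    sel <- as.character(data$trait) == tn
    keys[[tn]] <- data$value[sel][match(id_k, id_d[sel])]
  }
  keys
}

#' Read a trial dataset from CSV
#'
#' Reads either dialect written by [write_trial()] (auto-detected from the
#' header by default). Duplicate plot-by-trait rows and non-numeric values
#' are rejected with the offending keys / line numbers; factor levels are
#' taken in file order.
#'
#' @param path CSV path.
#' @param dialect `"auto"` (default), `"long"` or `"wide"`.
#' @return A `trial_data` data frame in long format.
#' @export
read_trial <- function(path, dialect = c("auto", "long", "wide")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("accession", "year", "block", "column")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))
  if (dialect == "auto") {
    dialect <- if (all(c("trait", "value") %in% names(raw))) "long" else "wide"
  }
  if (dialect == "long") {
    if (!all(c("trait", "value") %in% names(raw))) {
      stop("long dialect requires 'trait' and 'value' columns")
    }
    long <- raw
  } else {
    traits <- setdiff(names(raw), need)
    if (!length(traits)) stop("wide dialect has no trait columns")
    long <- do.call(rbind, lapply(traits, function(tn) {
      data.frame(raw[need], trait = tn, value = raw[[tn]],
                 stringsAsFactors = FALSE)
    }))
  }
  key <- paste(long$accession, long$year, long$block, long$trait)
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop("duplicate plot row(s) for key(s): ",
         paste(utils::head(unique(key[dup]), 3), collapse = "; "))
  }
  val <- suppressWarnings(as.numeric(long$value))
  bad <- which(is.na(val) & !is.na(long$value) &
                 long$value != "" & long$value != "NA")
  if (length(bad)) {
    stop("non-numeric value(s) at data line(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  out <- data.frame(
    accession = factor(long$accession, levels = unique(long$accession)),
    year = factor(long$year, levels = unique(long$year)),
    block = factor(long$block, levels = unique(long$block)),
    column = factor(long$column, levels = unique(long$column)),
    trait = factor(long$trait, levels = unique(long$trait)),
    value = val
  )
  class(out) <- c("trial_data", "data.frame")
  tj <- paste0(path, ".truth.json")
  if (file.exists(tj)) attr(out, "truth") <- jsonlite::read_json(tj)
  out
}
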