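#' Normalize indicator text
#'
#' NFKC unicode normalization (folding full-width latin and digits to their
#' half-width forms), lowercasing, and trimming of surrounding whitespace.
#' Applied to every name and abbreviation on corpus ingestion so that
#' variants differing only in width or case compare equal.
#'
#' @param x character vector.
#' @return normalized character vector; `NA` stays `NA`.
#' @export
normalizeIndicatorText <- function(x) {
  out <- stringi::stri_trans_nfkc(x)
  out <- stringi::stri_trans_tolower(out)
  trimws(out)
}

.emptyIndicatorTable <- function() {
  data.frame(id = character(), name = character(),
             abbreviation = character(), source_tag = character(),
             stringsAsFactors = FALSE)
}

.asIndicatorTable <- function(df, what) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!nrow(df)) return(.emptyIndicatorTable())
  if (!("abbreviation" %in% names(df))) df$abbreviation <- NA_character_
  if (!("source_tag" %in% names(df))) df$source_tag <- ""
  df$id <- as.character(df$id)
  df$name <- normalizeIndicatorText(as.character(df$name))
  ab <- normalizeIndicatorText(as.character(df$abbreviation))
  ab[!is.na(ab) & !nzchar(ab)] <- NA_character_  # empty on disk == absent
  df$abbreviation <- ab
  df$source_tag <- as.character(df$source_tag)
  rownames(df) <- NULL
  df[, c("id", "name", "abbreviation", "source_tag")]
}

#' Construct an IndicatorCorpus
#'
#' @param standards,nonstandards data.frames with columns `id`, `name` and
#'   optionally `abbreviation` (NA or empty = absent) and `source_tag`.
#' @param goldMap named character vector of gold standard ids keyed by
#'   non-standard id; missing entries are filled with `NA` (unlabeled).
#' @return an [IndicatorCorpus-class] object.
#' @export
indicatorCorpus <- function(standards, nonstandards,
                            goldMap = character()) {
  std <- .asIndicatorTable(standards, "standards")
  non <- .asIndicatorTable(nonstandards, "nonstandards")
  gm <- rep(NA_character_, nrow(non))
  names(gm) <- non$id
  if (length(goldMap)) {
    goldMap <- goldMap[!is.na(goldMap)]
    unknown <- setdiff(names(goldMap), non$id)
    if (length(unknown))
      stop("goldMap refers to unknown non-standard id: ", unknown[1L])
    gm[names(goldMap)] <- unname(goldMap)
  }
  new("IndicatorCorpus", standards = std, nonstandards = non, goldMap = gm)
}

#' @rdname IndicatorCorpus-class
#' @export
standards <- function(x) x@standards

#' @rdname IndicatorCorpus-class
#' @export
nonstandards <- function(x) x@nonstandards

#' @rdname IndicatorCorpus-class
#' @export
goldMap <- function(x) x@goldMap

#' Read an indicator corpus from TSV or JSONL
#'
#' The TSV dialect is UTF-8, tab-separated with a header row and no quoting
#' (tabs are forbidden inside values). JSONL holds one object per line.
#' Required columns/keys: `id`, `name`, `role` (`standard` or `nonstandard`);
#' optional: `abbreviation` (empty = absent), `gold_standard_id`,
#' `source_tag`.
#'
#' @param path file path.
#' @param format `"tsv"` or `"jsonl"`; default guessed from the extension.
#' @return an [IndicatorCorpus-class].
#' @export
readCorpus <- function(path, format = c("auto", "tsv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.jsonl$", path)) "jsonl" else "tsv"
  if (!file.exists(path)) stop("no such file: ", path)
  df <- if (format == "tsv") {
    utils::read.delim(path, sep = "\t", quote = "", header = TRUE,
                      colClasses = "character", encoding = "UTF-8",
                      na.strings = NULL, stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    recs <- lapply(lines, jsonlite::fromJSON)
    cols <- unique(unlist(lapply(recs, names)))
    as.data.frame(
      stats::setNames(lapply(cols, function(k)
        vapply(recs, function(r) {
          v <- r[[k]]
          if (is.null(v)) NA_character_ else as.character(v)
        }, character(1))), cols),
      stringsAsFactors = FALSE)
  }
  required <- c("id", "name", "role")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("corpus file lacks required column(s): ",
         paste(missing, collapse = ", "))
  dup <- df$id[duplicated(df$id)]
  if (length(dup)) stop("duplicate indicator id: ", dup[1L])
  emptyName <- which(!nzchar(trimws(df$name)) | is.na(df$name))
  if (length(emptyName))
    stop("empty indicator name at data row ", emptyName[1L])
  if (!all(df$role %in% c("standard", "nonstandard")))
    stop("role must be 'standard' or 'nonstandard'")
  std <- df[df$role == "standard", , drop = FALSE]
  non <- df[df$role == "nonstandard", , drop = FALSE]
  gm <- character()
  if ("gold_standard_id" %in% names(df)) {
    g <- non$gold_standard_id
    g[is.na(g) | !nzchar(g)] <- NA_character_
    keep <- !is.na(g)
    if (any(keep)) {
      bad <- setdiff(g[keep], std$id)
      if (length(bad)) stop("gold standard id not among standards: ", bad[1L])
      gm <- stats::setNames(g[keep], non$id[keep])
    }
  }
  indicatorCorpus(std, non, gm)
}

#' Write an indicator corpus to TSV or JSONL
#'
#' Inverse of [readCorpus()]: `readCorpus(writeCorpus(x, p), ...)` returns a
#' corpus identical to `x`. Absent abbreviations are written as empty fields.
#'
#' @param corpus an [IndicatorCorpus-class].
#' @param path output file path.
#' @param format `"tsv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
writeCorpus <- function(corpus, path, format = c("tsv", "jsonl")) {
  format <- match.arg(format)
  std <- standards(corpus); non <- nonstandards(corpus)
  std$role <- rep("standard", nrow(std))
  non$role <- rep("nonstandard", nrow(non))
  std$gold_standard_id <- rep(NA_character_, nrow(std))
  non$gold_standard_id <- unname(goldMap(corpus)[non$id])
  df <- rbind(std, non)
  df <- df[, c("id", "name", "role", "abbreviation", "gold_standard_id",
               "source_tag")]
  .writeTable(df, path, format)
  invisible(path)
}

.writeTable <- function(df, path, format) {
  for (k in names(df)) df[[k]][is.na(df[[k]])] <- ""
  if (format == "tsv") {
    hasTab <- vapply(df, function(col) any(grepl("\t", col)), logical(1))
    if (any(hasTab)) stop("tab character inside a value; TSV forbids this")
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = TRUE, fileEncoding = "")
  } else {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_len(nrow(df))) {
      rec <- as.list(df[i, , drop = FALSE])
      rec <- rec[nzchar(unlist(rec))]
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
    }
  }
}

#' Write predicted mappings
#'
#' Writes (non-standard id, standard id, probability) triples sorted by
#' non-standard id, then by descending probability. Round-trips through
#' [readMappings()].
#'
#' @param mappings data.frame with columns `nonstandard_id`, `standard_id`,
#'   `probability`.
#' @param path output file path.
#' @param format `"tsv"` or `"jsonl"`.
#' @return number of rows written, invisibly.
#' @export
writeMappings <- function(mappings, path, format = c("tsv", "jsonl")) {
  format <- match.arg(format)
  required <- c("nonstandard_id", "standard_id", "probability")
  if (!all(required %in% names(mappings)))
    stop("mappings must have columns ", paste(required, collapse = ", "))
  mappings <- as.data.frame(mappings, stringsAsFactors = FALSE)
  ord <- order(mappings$nonstandard_id, -mappings$probability,
               mappings$standard_id)
  mappings <- mappings[ord, required, drop = FALSE]
  mappings$probability <- formatC(mappings$probability, digits = 10,
                                  format = "g")
  .writeTable(mappings, path, format)
  invisible(nrow(mappings))
}

#' @rdname writeMappings
#' @export
readMappings <- function(path, format = c("auto", "tsv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.jsonl$", path)) "jsonl" else "tsv"
  df <- if (format == "tsv") {
    utils::read.delim(path, sep = "\t", quote = "", header = TRUE,
                      colClasses = "character", encoding = "UTF-8",
                      stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    do.call(rbind, lapply(lines, function(l)
      as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)))
  }
  if (is.null(df) || !nrow(df))
    return(data.frame(nonstandard_id = character(),
                      standard_id = character(),
                      probability = numeric(), stringsAsFactors = FALSE))
  df$probability <- as.numeric(df$probability)
  rownames(df) <- NULL
  df
}

#' Combine an indicator's name and abbreviation into one string
#'
#' The classifier works on a single text per indicator, the concatenation of
#' its name and (when present) its abbreviation, so one model covers both
#' fields. When the abbreviation is absent the name is returned unchanged.
#'
#' @param name character vector of names.
#' @param abbreviation character vector of abbreviations; `NA` = absent.
#' @param separator string placed between name and abbreviation.
#' @return character vector of combined texts.
#' @examples
#' combineNameAbbrev("酸碱度", "ph")   # name + " " + abbreviation
#' combineNameAbbrev("酸碱度", NA)     # name alone
#' @export
combineNameAbbrev <- function(name, abbreviation = NA_character_,
                              separator = " ") {
  stopifnot(is.character(name), length(name) >= 1L)
  abbreviation <- rep_len(as.character(abbreviation), length(name))
  ifelse(is.na(abbreviation), name,
         paste(name, abbreviation, sep = separator))
}

#' @rdname combineNameAbbrev
#' @param table an indicator data.frame (see [IndicatorCorpus-class]).
#' @export
combinedTexts <- function(table, separator = " ") {
  stats::setNames(
    combineNameAbbrev(table$name, table$abbreviation, separator),
    table$id)
}
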