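# Delimited-text I/O. All matrices travel as CSV/TSV (optionally gzipped):
# first column sample ID, header row of probe/protein/score IDs.

#' Read / write a wide sample-by-feature table
#'
#' @param path File path; the delimiter is inferred from the extension
#'   (`.csv[.gz]` comma, otherwise tab).
#' @param id_col Name given to the first column (`"sample_id"`); `NULL`
#'   keeps the file's own header, e.g. for long-format tables.
#' @return A tibble whose first column is `sample_id`.
#' @export
read_matrix_table <- function(path, id_col = "sample_id") {
  if (!file.exists(path)) abort(sprintf("input file not found: %s", path))
  delim <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  out <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (!is.null(id_col)) names(out)[1] <- id_col
  out
}

#' @rdname read_matrix_table
#' @param data Wide data frame (first column sample IDs) or matrix.
#' @export
write_matrix_table <- function(data, path) {
  if (is.matrix(data)) data <- matrix_to_tibble(data)
  delim <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  readr::write_delim(data, path, delim = delim)
  invisible(path)
}

#' Read a survival table
#'
#' Expects columns `sample_id`, `disease`, `time_years`, `event` and
#' optionally `family_id`.
#'
#' @param path File path (CSV or TSV).
#' @return Tibble of survival records.
#' @export
read_survival_table <- function(path) {
  out <- read_matrix_table(path)
  need <- c("sample_id", "disease", "time_years", "event")
  miss <- setdiff(need, names(out))
  if (length(miss)) {
    abort(sprintf("survival table %s: missing columns %s", path,
                  paste(miss, collapse = ", ")))
  }
  if (any(!out$event %in% c(0, 1))) abort("survival table: event must be 0/1")
  if (any(!is.finite(out$time_years)) || any(out$time_years <= 0)) {
    abort("survival table: time_years must be finite and positive")
  }
  out
}

#' Serialize EpiScore weights to CSV
#'
#' Writes the sparse weight table as CSV with columns `episcore_id`,
#' `protein_id`, `panel`, `cpg`, `weight`, preceded by a `#`-prefixed sidecar
#' header carrying the per-score training metadata as JSON. Weights are
#' written with full precision (`digits = 17`) so the round trip is
#' bit-exact.
#'
#' @param weights An [episcore_weights()] table.
#' @param path Output path.
#' @export
write_episcore_weights <- function(weights, path) {
  if (!inherits(weights, "episcore_weights")) weights <- episcore_weights(weights)
  meta <- attr(weights, "training_meta")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# episcore weight file v1", con)
  if (!is.null(meta)) {
    writeLines(paste0("# meta: ", jsonlite::toJSON(meta, digits = NA)), con)
  }
  writeLines("episcore_id,protein_id,panel,cpg,weight", con)
  if (nrow(weights)) {
    writeLines(sprintf("%s,%s,%s,%s,%s", weights$episcore_id,
                       weights$protein_id, weights$panel, weights$cpg,
                       formatC(weights$weight, digits = 17, format = "g")),
               con)
  }
  invisible(path)
}

#' Read an EpiScore weight file
#'
#' Inverse of [write_episcore_weights()]. Malformed rows, non-numeric
#' weights and duplicate (episcore, cpg) pairs are parse errors naming the
#' offending line; unknown extra columns are accepted with a warning.
#'
#' @param path Path to a weight CSV.
#' @return An [episcore_weights()] table (training metadata restored when
#'   present in the header).
#' @export
read_episcore_weights <- function(path) {
  if (!file.exists(path)) abort(sprintf("weight file not found: %s", path))
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  n_hdr <- if (any(!hdr)) which(!hdr)[1] - 1 else length(lines)
  meta <- NULL
  meta_line <- grep("^# meta: ", lines[seq_len(n_hdr)], value = TRUE)
  if (length(meta_line)) {
    meta <- as_tibble(jsonlite::fromJSON(sub("^# meta: ", "", meta_line[1])))
  }
  body <- lines[!hdr]
  if (length(body) < 1) abort(sprintf("weight file %s: no header row", path))
  cols <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  need <- c("episcore_id", "protein_id", "panel", "cpg", "weight")
  miss <- setdiff(need, cols)
  if (length(miss)) {
    abort(sprintf("weight file %s: missing columns %s", path,
                  paste(miss, collapse = ", ")))
  }
  extra <- setdiff(cols, need)
  if (length(extra)) {
    warn(sprintf("weight file %s: ignoring unknown columns %s", path,
                 paste(extra, collapse = ", ")))
  }
  rows <- body[-1]
  line_no <- n_hdr + 1 + seq_along(rows)
  parts <- strsplit(rows, ",", fixed = TRUE)
  bad <- which(lengths(parts) != length(cols))
  if (length(bad)) {
    abort(sprintf("weight file %s: malformed row at line %d", path, line_no[bad[1]]))
  }
  tab <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(tab) <- cols
  w <- suppressWarnings(as.numeric(tab$weight))
  if (length(w) && any(is.na(w))) {
    abort(sprintf("weight file %s: non-numeric weight at line %d", path,
                  line_no[which(is.na(w))[1]]))
  }
  tab$weight <- w
  dup <- duplicated(tab[c("episcore_id", "cpg")])
  if (any(dup)) {
    abort(sprintf("weight file %s: duplicate (episcore, cpg) pair at line %d",
                  path, line_no[which(dup)[1]]))
  }
  episcore_weights(as_tibble(tab[need]), meta = meta)
}
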