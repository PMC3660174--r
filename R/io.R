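#' Read a Sanger-offset FASTQ file into a read table
#'
#' Parses a 4-line-per-record FASTQ file (Phred+33 quality encoding) into a
#' tibble with one row per read. Files are consumed in chunks so memory use is
#' bounded by the chunk size, not the file size.
#'
#' Quality characters outside the Phred+33 range for quality values 0--60 are
#' rejected; in particular inputs that look Phred+64-encoded (quality
#' characters beyond `]`) raise an error rather than being silently
#' re-interpreted.
#'
#' @param path Path to a FASTQ file.
#' @param chunk_size Number of records read per chunk.
#' @return A tibble with columns `read_id` (character), `sequence`
#'   (character, uppercase ACGTN) and `qualities` (list of integer vectors,
#'   one Phred score per base).
#' @export
read_fastq <- function(path, chunk_size = 10000L) {
  if (!file.exists(path)) abort(paste0("FASTQ file not found: ", path))
  con <- file(path, open = "r")
  on.exit(close(con))
  chunks <- list()
  line_no <- 0L
  repeat {
    lines <- readLines(con, n = 4L * chunk_size)
    if (length(lines) == 0L) break
    if (length(lines) %% 4L != 0L) {
      abort(sprintf(
        "malformed FASTQ: truncated 4-line record ending at line %d",
        line_no + length(lines)
      ))
    }
    idx <- seq(1L, length(lines), by = 4L)
    hdr <- lines[idx]
    seqs <- toupper(lines[idx + 1L])
    plus <- lines[idx + 2L]
    qual <- lines[idx + 3L]
    bad <- which(!startsWith(hdr, "@"))
    if (length(bad) > 0L) {
      abort(sprintf(
        "malformed FASTQ: expected '@' header at line %d",
        line_no + (bad[1] - 1L) * 4L + 1L
      ))
    }
    bad <- which(!startsWith(plus, "+"))
    if (length(bad) > 0L) {
      abort(sprintf(
        "malformed FASTQ: expected '+' separator at line %d",
        line_no + (bad[1] - 1L) * 4L + 3L
      ))
    }
    bad <- which(nchar(seqs) != nchar(qual))
    if (length(bad) > 0L) {
      abort(sprintf(
        "malformed FASTQ: sequence/quality length mismatch at line %d",
        line_no + (bad[1] - 1L) * 4L + 2L
      ))
    }
    quals <- lapply(qual, function(q) {
      if (nchar(q) == 0L) return(integer(0))
      utf8ToInt(q) - 33L
    })
    qv <- unlist(quals, use.names = FALSE)
    if (length(qv) > 0L && (min(qv) < 0L || max(qv) > 60L)) {
      abort(paste0(
        "quality characters outside the Phred+33 range for QV 0-60; ",
        "offset-64 encoded input is not supported"
      ))
    }
    ids <- sub("\\s.*$", "", substring(hdr, 2L))
    chunks[[length(chunks) + 1L]] <- tibble(
      read_id = ids, sequence = seqs, qualities = quals
    )
    line_no <- line_no + length(lines)
  }
  if (length(chunks) == 0L) {
    return(tibble(
      read_id = character(0), sequence = character(0), qualities = list()
    ))
  }
  dplyr::bind_rows(chunks)
}

#' Write a read table to FASTQ (Phred+33)
#'
#' @param reads Tibble with `read_id`, `sequence`, `qualities` columns, as
#'   produced by [read_fastq()] or the simulators.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual_str <- vapply(
    reads$qualities,
    function(q) if (length(q) == 0L) "" else intToUtf8(q + 33L),
    character(1)
  )
  out <- rbind(
    paste0("@", reads$read_id), reads$sequence, "+", qual_str
  )
  writeLines(as.vector(out), path)
  invisible(path)
}

#' Read a multi-FASTA file
#'
#' Sequences are uppercased; in `mode = "dna"` any `U` is mapped to `T`, in
#' `mode = "rna"` the letters are preserved as read. Duplicate identifiers
#' (first whitespace-delimited token of the header) are an error.
#'
#' @param path Path to a FASTA file.
#' @param mode `"dna"` (default) or `"rna"`.
#' @return A tibble with columns `id`, `description` (full header) and
#'   `sequence`.
#' @export
read_fasta <- function(path, mode = c("dna", "rna")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  ss <- Biostrings::readBStringSet(path)
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    abort(paste0("duplicate FASTA id(s): ", paste(dup, collapse = ", ")))
  }
  seqs <- toupper(as.character(ss))
  if (mode == "dna") seqs <- gsub("U", "T", seqs, fixed = TRUE)
  tibble(id = ids, description = headers, sequence = unname(seqs))
}

#' Write sequences to FASTA
#'
#' @param x Tibble with `id` and `sequence` columns (a `description` column,
#'   if present, is appended to the header), or a named character vector.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (is.character(x)) x <- tibble(id = names(x), sequence = unname(x))
  hdr <- paste0(">", x$id)
  if ("description" %in% names(x) && !all(x$description == x$id)) {
    extra <- ifelse(x$description == x$id, "", paste0(" ", x$description))
    hdr <- paste0(hdr, extra)
  }
  lines <- unlist(purrr::map2(hdr, x$sequence, function(h, s) {
    c(h, substring(s, seq(1L, nchar(s), by = width),
                   pmin(seq(1L, nchar(s), by = width) + width - 1L, nchar(s))))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Write a report table as TSV with a JSON mirror
#'
#' Tables are tab-separated with a header row and deterministic column order
#' (as given). Percentage columns (names containing `pct` or `percent`) are
#' rendered with exactly two decimals. A JSON mirror with the same basename
#' and a `.json` extension is written alongside for machine reading.
#'
#' @param rows A data frame.
#' @param path Output TSV path.
#' @param json Write the JSON mirror (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_report_table <- function(rows, path, json = TRUE) {
  out <- as.data.frame(rows)
  pct_cols <- grepl("pct|percent", names(out), ignore.case = TRUE)
  for (j in which(pct_cols)) {
    if (is.numeric(out[[j]])) out[[j]] <- sprintf("%.2f", out[[j]])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  if (json) {
    jpath <- sub("\\.[^.]*$", ".json", path)
    if (identical(jpath, path)) jpath <- paste0(path, ".json")
    jsonlite::write_json(as.data.frame(rows), jpath,
                         dataframe = "rows", digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read back a TSV report table
#'
#' @param path Path written by [write_report_table()].
#' @return A tibble.
#' @export
read_report_table <- function(path) {
  as_tibble(read.delim(path, sep = "\t", check.names = FALSE,
                       stringsAsFactors = FALSE))
}
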