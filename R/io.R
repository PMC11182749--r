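## On-disk formats. Peaks are held 1-based inclusive in memory and
## converted to 0-based half-open BED on write (and back on read).

#' Read a BED file into a peak data.frame
#'
#' @param path BED3/BED6 file (uncompressed, tab separated).
#' @return data.frame with `chrom`, `start`, `end` (1-based inclusive)
#'   and, when present, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  if (ncol(df) >= 5) names(df)[5] <- "score"
  if (ncol(df) >= 6) names(df)[6] <- "strand"
  df$start <- df$start + 1L          # BED is 0-based half-open
  df
}

#' Write peaks as BED6
#'
#' @param peaks data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive) and optional `name`, `score`, `strand`.
#' @param path output file.
#' @export
write_bed <- function(peaks, path) {
  out <- data.frame(chrom = peaks$chrom,
                    start = peaks$start - 1L,
                    end = peaks$end,
                    name = peaks$name %||% sprintf("peak_%05d", seq_len(nrow(peaks))),
                    score = peaks$score %||% 0,
                    strand = peaks$strand %||% ".")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a JASPAR-style PWM file
#'
#' Parses the four-row count format
#' (`>ID name` then `A [ counts ]` etc.).
#'
#' @param path PWM file.
#' @return Named list of PWMs; each a list with `id`, `name` and a
#'   4 x L `counts` matrix with rows A, C, G, T.
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  out <- list()
  for (s in seq_along(starts)) {
    hdr <- strsplit(sub("^>", "", lines[starts[s]]), "\\s+")[[1]]
    block <- lines[(starts[s] + 1L):(starts[s] + 4L)]
    rows <- lapply(block, function(l) {
      s <- sub("^\\s*[ACGTacgt]", "", l)
      as.numeric(regmatches(s, gregexpr("[0-9.]+", s))[[1]])
    })
    counts <- do.call(rbind, rows)
    rownames(counts) <- toupper(substr(trimws(block), 1, 1))
    counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
    id <- hdr[1]
    out[[id]] <- list(id = id, name = if (length(hdr) > 1) hdr[2] else id,
                      counts = counts)
  }
  out
}

#' Write PWMs in JASPAR count format
#'
#' @param pwms list of PWMs as returned by [read_jaspar()].
#' @param path output file.
#' @export
write_jaspar <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(sprintf(">%s %s", p$id, p$name), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(sprintf("%s  [ %s ]", b,
                         paste(format(p$counts[b, ]), collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read FASTA sequences as a named character vector
#' @param path FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Write named sequences to FASTA
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

write_tsv <- function(df, path, row_names = FALSE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = row_names, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}
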