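#' Sequence database: concatenated residue text with protein pointers
#'
#' A `sequence_db` stores a set of proteins as one concatenated text in which
#' every protein is followed by a sentinel character (`"$"`, lexicographically
#' smaller than any residue). Protein `i` occupies the 0-based half-open slice
#' `[start[i], start[i+1] - 1)` of `txt`, with its sentinel at
#' `start[i+1] - 1`.
#'
#' @param seqs character vector of cleaned residue strings (no sentinels).
#' @param ids character vector of protein identifiers, same length as `seqs`.
#' @return An object of class `sequence_db`: a list with elements
#'   `txt` (single string), `start` (integer vector of 0-based offsets,
#'   length `n_proteins + 1`, last entry = `nchar(txt)`), `ids`,
#'   `n_proteins` and `n_residues` (residues excluding sentinels).
#' @examples
#' db <- sequence_db(c("AB", "AC"), c("p1", "p2"))
#' db$txt    # "AB$AC$"
#' db$start  # 0 3 6
#' @export
sequence_db <- function(seqs, ids = NULL) {
  if (length(seqs) == 0L) stop("no sequences")
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  stopifnot(length(ids) == length(seqs))
  if (any(nchar(seqs) == 0L)) stop("zero-length sequence")
  if (any(grepl(SENTINEL, seqs, fixed = TRUE)))
    stop("sentinel character inside a sequence")
  lens <- nchar(seqs)
  start <- c(0L, cumsum(lens + 1L))
  structure(
    list(txt = paste0(paste0(seqs, SENTINEL), collapse = ""),
         start = as.integer(start),
         ids = as.character(ids),
         n_proteins = length(seqs),
         n_residues = sum(lens)),
    class = "sequence_db")
}

#' @export
print.sequence_db <- function(x, ...) {
  cat(sprintf("sequence_db: %d proteins, %d residues (text %d bytes)\n",
              x$n_proteins, x$n_residues, nchar(x$txt)))
  invisible(x)
}

#' Extract the residue string of one protein
#'
#' @param db a [sequence_db()].
#' @param i protein index (1-based).
#' @return Residue string without the sentinel.
#' @export
db_sequence <- function(db, i) {
  stopifnot(i >= 1L, i <= db$n_proteins)
  substr(db$txt, db$start[i] + 1L, db$start[i + 1L] - 1L)
}

clean_residues <- function(x) {
  x <- toupper(x)
  x <- gsub("[*-]", "", x)
  # keep the letters BLOSUM-style scoring understands; rare residues
  # (U, O, J) and anything non-standard become 'X'
  keep <- c(AA_STANDARD, "B", "Z", "X")
  chars <- strsplit(x, "", fixed = TRUE)
  vapply(chars, function(ch) {
    ch[!(ch %in% keep)] <- "X"
    paste0(ch, collapse = "")
  }, character(1))
}

#' Read a protein FASTA file into a sequence database
#'
#' Residues are uppercased; `*` and `-` are removed; characters outside the
#' scored amino-acid alphabet (20 standard letters plus B, Z, X; rare U/O/J
#' included) are mapped to `X`. Identifiers are the first whitespace-delimited
#' token of each header. Records that are empty after cleaning are skipped
#' with a warning and listed in the `skipped` attribute of the result.
#'
#' @param path FASTA file path.
#' @param strip_annotation keep only the first header token as the id.
#' @return A [sequence_db()]; attribute `skipped` holds ids of dropped records.
#' @export
load_fasta <- function(path, strip_annotation = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no sequences")
  ids <- names(set)
  if (strip_annotation) ids <- sub("\\s.*$", "", ids)
  seqs <- clean_residues(as.character(set))
  empty <- nchar(seqs) == 0L
  skipped <- character(0)
  if (any(empty)) {
    skipped <- ids[empty]
    warning(sprintf("skipped %d record(s) with no residues after cleaning: %s",
                    sum(empty), paste(skipped, collapse = ", ")))
    seqs <- seqs[!empty]
    ids <- ids[!empty]
  }
  if (length(seqs) == 0L) stop("no sequences")
  db <- sequence_db(seqs, ids)
  attr(db, "skipped") <- skipped
  db
}

#' Protein owning a text position
#'
#' Maps a 0-based offset in the concatenated text to the protein whose slice
#' (including its trailing sentinel) contains it, by binary search over the
#' start pointers. Sentinels belong to the preceding protein so that the
#' suffix-to-protein map is total.
#'
#' @param db a [sequence_db()].
#' @param s 0-based text offset (vectorised).
#' @return Protein index (1-based).
#' @export
protein_of_position <- function(db, s) {
  n <- nchar(db$txt)
  if (any(s < 0L | s >= n)) stop("position out of range")
  findInterval(s, db$start)
}

#' Persist / restore a sequence database
#'
#' The text is stored at exactly one byte per character (`txt.bin`), the start
#' pointers as 8-byte integers (`start.bin`) and the identifiers as plain text
#' (`ids.txt`). The round trip is lossless.
#'
#' @param db a [sequence_db()].
#' @param dir directory to write into (created if needed).
#' @return `save_db` returns `dir` invisibly; `load_db` the restored database.
#' @export
save_db <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeBin(charToRaw(db$txt), file.path(dir, "txt.bin"))
  con <- file(file.path(dir, "start.bin"), "wb")
  writeBin(as.numeric(db$start), con, size = 8)
  close(con)
  writeLines(db$ids, file.path(dir, "ids.txt"))
  invisible(dir)
}

#' @rdname save_db
#' @export
load_db <- function(dir) {
  paths <- file.path(dir, c("txt.bin", "start.bin", "ids.txt"))
  missing <- !file.exists(paths)
  if (any(missing))
    stop("missing database file(s): ", paste(basename(paths[missing]), collapse = ", "))
  nbytes <- file.size(paths[1])
  txt <- rawToChar(readBin(paths[1], "raw", n = nbytes))
  start <- as.integer(readBin(paths[2], "numeric", n = file.size(paths[2]) / 8, size = 8))
  ids <- readLines(paths[3])
  if (length(start) != length(ids) + 1L || start[length(start)] != nchar(txt))
    stop("corrupted database artifact in ", dir, " (start.bin inconsistent with txt.bin)")
  structure(
    list(txt = txt, start = start, ids = ids,
         n_proteins = length(ids),
         n_residues = nchar(txt) - length(ids)),
    class = "sequence_db")
}
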