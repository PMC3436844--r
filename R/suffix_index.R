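#' Build a suffix array
#'
#' Lexicographic order of all suffixes of the concatenated text, computed by
#' the SA-IS induced-sorting algorithm (linear time and space). A suffix that
#' is a proper prefix of another compares smaller, so with the sentinel
#' convention all suffix comparisons are strict.
#'
#' @param txt concatenated text ending in a sentinel.
#' @return Integer vector `sa`; `sa[l]` (1-based R index `l`) is the 0-based
#'   text offset of the `(l-1)`-th smallest suffix.
#' @examples
#' build_suffix_array("BANANAS$")  # 7 1 3 5 0 2 4 6
#' @export
build_suffix_array <- function(txt) {
  stopifnot(is.character(txt), length(txt) == 1L, nchar(txt) > 0L)
  if (substr(txt, nchar(txt), nchar(txt)) != SENTINEL)
    stop("text must end in the sentinel")
  .sais_sa(charToRaw(txt))
}

#' Invert a suffix array
#'
#' @param sa suffix array (0-based offsets).
#' @return Integer vector `isa` with `isa[s+1]` = 0-based lexicographic rank
#'   of the suffix starting at offset `s`; satisfies `isa[sa + 1] == 0:(n-1)`.
#' @export
build_isa <- function(sa) {
  n <- length(sa)
  if (n == 0L || !setequal(sa, 0:(n - 1L)))
    stop("sa is not a permutation of 0..n-1")
  isa <- integer(n)
  isa[sa + 1L] <- 0:(n - 1L)
  isa
}

#' Protein labels of suffixes in lexicographic order
#'
#' @param sa suffix array built on `db$txt`.
#' @param db the [sequence_db()] the array was built on.
#' @return Integer vector `sap`; `sap[l]` is the (1-based) protein owning the
#'   suffix at lexicographic rank `l - 1`. Sentinel-initial suffixes are
#'   assigned to the preceding protein.
#' @export
build_sap <- function(sa, db) {
  if (length(sa) != nchar(db$txt)) stop("sa / text length mismatch")
  protein_of_position(db, sa)
}

#' Full suffix index of a sequence database
#'
#' @param db a [sequence_db()].
#' @return An object of class `suffix_index`: list with `sa`, `isa`, `sap`
#'   and `n` (text length).
#' @export
suffix_index <- function(db) {
  sa <- build_suffix_array(db$txt)
  structure(list(sa = sa, isa = build_isa(sa), sap = build_sap(sa, db),
                 n = length(sa)),
            class = "suffix_index")
}

#' @export
print.suffix_index <- function(x, ...) {
  cat(sprintf("suffix_index over %d positions\n", x$n))
  invisible(x)
}

#' Merge query suffixes into the database suffix order
#'
#' For every query suffix `q` starting at 0-based query offset `s_Q`, finds
#' the largest database rank `l` whose suffix is `<= q` (`-1` if `q` precedes
#' every database suffix). Both suffix orders are already sorted, so a single
#' simultaneous pass (merge step) suffices; character comparisons are bounded
#' in practice by common-prefix lengths.
#'
#' @param db_index [suffix_index()] of the database.
#' @param db database [sequence_db()].
#' @param qdb query [sequence_db()].
#' @param q_sa optional precomputed suffix array of `qdb$txt`.
#' @return An object of class `query_mapping`: list with `isa_mapped`
#'   (integer vector over query offsets, 0-based ranks, `-1` allowed) and
#'   `m` (query text length).
#' @export
map_query_suffixes <- function(db_index, db, qdb, q_sa = NULL) {
  if (is.null(q_sa)) q_sa <- build_suffix_array(qdb$txt)
  isa_mapped <- .merge_map(charToRaw(db$txt), db_index$sa,
                           charToRaw(qdb$txt), q_sa)
  structure(list(isa_mapped = isa_mapped, m = length(isa_mapped)),
            class = "query_mapping")
}

#' Persist / restore suffix index search artifacts
#'
#' Disk layout of the search-time artifacts: `sap` at 4 bytes per entry and
#' `isa_mapped` at 8 bytes per entry (`8m + 4n` bytes in total for database
#' length `n` and query length `m`), plus `sa` at 8 bytes per entry for
#' completeness.
#'
#' @param index a [suffix_index()].
#' @param mapping a [map_query_suffixes()] result (or `NULL` to skip).
#' @param dir directory to write into.
#' @return `save_index` returns `dir` invisibly; `load_index` a list with
#'   `index` and `mapping`.
#' @export
save_index <- function(index, mapping = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(dir, "sa.bin"), "wb")
  writeBin(as.numeric(index$sa), con, size = 8); close(con)
  con <- file(file.path(dir, "sap.bin"), "wb")
  writeBin(index$sap, con, size = 4); close(con)
  if (!is.null(mapping)) {
    con <- file(file.path(dir, "isa_mapped.bin"), "wb")
    writeBin(as.numeric(mapping$isa_mapped), con, size = 8); close(con)
  }
  invisible(dir)
}

#' @rdname save_index
#' @export
load_index <- function(dir) {
  sa_p <- file.path(dir, "sa.bin")
  sap_p <- file.path(dir, "sap.bin")
  if (!file.exists(sa_p) || !file.exists(sap_p))
    stop("missing index file(s) in ", dir)
  sa <- as.integer(readBin(sa_p, "numeric", n = file.size(sa_p) / 8, size = 8))
  sap <- readBin(sap_p, "integer", n = file.size(sap_p) / 4, size = 4)
  if (length(sa) != length(sap)) stop("corrupted index artifact in ", dir)
  index <- structure(list(sa = sa, isa = build_isa(sa), sap = sap,
                          n = length(sa)),
                     class = "suffix_index")
  mapping <- NULL
  im_p <- file.path(dir, "isa_mapped.bin")
  if (file.exists(im_p)) {
    im <- as.integer(readBin(im_p, "numeric", n = file.size(im_p) / 8, size = 8))
    mapping <- structure(list(isa_mapped = im, m = length(im)),
                         class = "query_mapping")
  }
  list(index = index, mapping = mapping)
}
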