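## Internal helpers: sequence I/O, RNG scoping, small validators.

#' The 20-letter amino-acid alphabet used by profile models
#' @return Character vector of the 20 standard residues.
#' @export
aa_alphabet <- function() .aa_alphabet()

## Run `expr` under a derived seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  seed <- as.integer(seed %% .Machine$integer.max)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

## Small deterministic hash of a string, for per-(species, component)
## substreams derived from one master seed.  Kept well below 2^31.
str_seed <- function(seed, ...) {
  s <- paste(..., sep = "/")
  h <- 0
  for (k in utf8ToInt(s)) h <- (h * 31 + k) %% 1999999973
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

assert_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    abort(sprintf("`%s` must lie in [0, 1]", name))
  invisible(x)
}

## FASTA helpers ------------------------------------------------------------

#' Read an amino-acid FASTA file into a named character vector
#' @param path Path to an (uncompressed) FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write a named character vector of sequences as FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::AAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Read a multiple sequence alignment (FASTA or Stockholm)
#'
#' FASTA alignments are read with Biostrings. Stockholm (the usual HMM seed
#' alignment format) is parsed by a minimal reader covering the single- and
#' multi-block layouts: sequence lines `name  ALIGNED`, `#` annotations and
#' the `//` terminator.
#'
#' @param path Path to the alignment.
#' @param format "auto" (sniff the first line), "fasta" or "stockholm".
#' @return Named character vector of equal-length aligned sequences.
#' @export
read_msa <- function(path, format = c("auto", "fasta", "stockholm")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (startsWith(first, "# STOCKHOLM")) "stockholm" else "fasta"
  }
  if (format == "fasta") return(read_fasta(path))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "//") &
                   nzchar(trimws(lines))]
  if (!length(lines)) abort("empty Stockholm alignment")
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    abort(sprintf("malformed Stockholm sequence line %d", bad[[1]]))
  nm <- vapply(parts, `[[`, "", 1L)
  sq <- vapply(parts, `[[`, "", 2L)
  out <- vapply(split(sq, factor(nm, levels = unique(nm))),
                paste0, "", collapse = "")
  if (length(unique(nchar(out))) != 1L)
    abort("ragged Stockholm alignment: sequences differ in aligned length")
  toupper(gsub("[.]", "-", out))
}

## Interval arithmetic (half-open, 0-based) ---------------------------------

## Merge half-open intervals (2-col matrix) into disjoint sorted intervals.
interval_merge <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0) return(matrix(numeric(0), ncol = 2))
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- list(); cur_s <- iv[1, 1]; cur_e <- iv[1, 2]
  if (nrow(iv) > 1) for (k in 2:nrow(iv)) {
    if (iv[k, 1] <= cur_e) cur_e <- max(cur_e, iv[k, 2])
    else { out[[length(out) + 1]] <- c(cur_s, cur_e); cur_s <- iv[k, 1]; cur_e <- iv[k, 2] }
  }
  out[[length(out) + 1]] <- c(cur_s, cur_e)
  do.call(rbind, out)
}

## Total length of the union of half-open intervals given as 2-col matrix.
interval_union_length <- function(iv) {
  m <- interval_merge(iv)
  if (!nrow(m)) return(0L)
  sum(m[, 2] - m[, 1])
}

## Length of intersection of one interval with a union of intervals.
interval_overlap_length <- function(s, e, iv) {
  if (is.null(iv) || nrow(iv) == 0) return(0L)
  sum(pmax(0, pmin(e, iv[, 2]) - pmax(s, iv[, 1])))
}
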