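# Internal coordinate convention: 0-based, half-open, 5'->3' on the mature
# transcript. Conversions to 1-based formats (GTF, SAM) happen only at file
# boundaries.

#' IUPAC degenerate nucleotide codes (RNA alphabet)
#'
#' Named list mapping each IUPAC code to the set of concrete RNA bases it
#' stands for (K = G/U, W = A/U, N = any, ...). Motifs and extracted windows
#' are handled as RNA; on-disk sequences use the DNA alphabet.
#'
#' @format Named list of character vectors.
#' @export
IUPAC_RNA <- list(
  A = "A", C = "C", G = "G", U = "U",
  R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"), W = c("A", "U"),
  K = c("G", "U"), M = c("A", "C"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "U")
)

#' Convert between DNA and RNA alphabets
#'
#' @param x character vector of sequences.
#' @return `x` with T<->U swapped (case preserved).
#' @export
dna_to_rna <- function(x) chartr("Tt", "Uu", x)

#' @rdname dna_to_rna
#' @export
rna_to_dna <- function(x) chartr("Uu", "Tt", x)

iupac_chars <- function(consensus) {
  chars <- strsplit(toupper(consensus), "")[[1]]
  bad <- setdiff(chars, names(IUPAC_RNA))
  if (length(bad))
    stop("unknown IUPAC code(s) in consensus '", consensus, "': ",
         paste(unique(bad), collapse = ", "))
  chars
}

iupac_regex <- function(consensus) {
  chars <- iupac_chars(consensus)
  paste0(vapply(chars, function(ch) {
    s <- IUPAC_RNA[[ch]]
    if (length(s) == 1L) s else paste0("[", paste(s, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' Match a degenerate IUPAC consensus against a sequence
#'
#' Standard IUPAC semantics on the given strand only; overlapping matches are
#' all reported. The sequence may be in DNA or RNA alphabet.
#'
#' @param sequence a single nucleotide sequence.
#' @param consensus IUPAC consensus string (RNA alphabet).
#' @return Integer vector of 0-based match offsets (possibly empty).
#' @examples
#' match_consensus("AUGAAUU", "AUKAAWU")  # 0
#' match_consensus("AUCAAUU", "AUKAAWU")  # integer(0): C is not in K
#' @export
match_consensus <- function(sequence, consensus) {
  stopifnot(length(sequence) == 1L)
  seq_rna <- dna_to_rna(toupper(sequence))
  rx <- paste0("(?=", iupac_regex(consensus), ")")
  m <- gregexpr(rx, seq_rna, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L
}

# one concrete expansion of a degenerate consensus, drawn uniformly per
# degenerate position under the current RNG state (RNA alphabet)
expand_iupac <- function(consensus) {
  chars <- iupac_chars(consensus)
  paste0(vapply(chars, function(ch) {
    s <- IUPAC_RNA[[ch]]
    if (length(s) == 1L) s else sample(s, 1L)
  }, character(1)), collapse = "")
}

# ---- CIGAR helpers -----------------------------------------------------------

parse_cigar <- function(cigar) {
  if (is.na(cigar) || !nzchar(cigar)) stop("empty CIGAR string")
  toks <- regmatches(cigar, gregexpr("[0-9]+[A-Za-z=]", cigar))[[1]]
  if (paste(toks, collapse = "") != cigar)
    stop("malformed CIGAR string: '", cigar, "'")
  op <- sub("^[0-9]+", "", toks)
  len <- as.integer(sub("[A-Za-z=]$", "", toks))
  if (any(len < 1L)) stop("CIGAR op with length < 1 in '", cigar, "'")
  if (length(op) > 1L && any(op[-1] == op[-length(op)]))
    stop("adjacent CIGAR ops share the same code in '", cigar, "'")
  data.frame(op = op, len = len, stringsAsFactors = FALSE)
}

# reference-space footprint length (M and D consume the transcript)
cigar_ref_len <- function(ops) sum(ops$len[ops$op %in% c("M", "D")])

cigar_string <- function(ops) paste0(ops$len, ops$op, collapse = "")

`%||%` <- function(a, b) if (is.null(a)) b else a
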