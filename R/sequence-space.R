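#' Define a sequence space
#'
#' The space of all `A^L` strings of length `L` over an ordered alphabet, with
#' edges between strings at Hamming distance one (single point mutations).
#' The nucleotide alphabet `"ACGT"` (`A = 4`) is the default; binary alphabets
#' (`A = 2`) are useful for exhaustively testable toy spaces.
#'
#' @param L Sequence length (integer, >= 1).
#' @param A Alphabet size (integer, >= 2). Ignored when `alphabet` is given.
#' @param alphabet Optional character vector of distinct single characters; its
#'   order fixes the deterministic neighbor ordering used throughout.
#'
#' @return An object of class `seq_space` with fields `L`, `A`, `alphabet`.
#' @examples
#' sp <- seq_space(8)
#' space_size(sp)       # 4^8 = 65536, exactly
#' @export
seq_space <- function(L, A = 4, alphabet = NULL) {
  stopifnot(is.numeric(L), length(L) == 1L, L >= 1, L == floor(L))
  if (is.null(alphabet)) {
    stopifnot(is.numeric(A), length(A) == 1L, A >= 2, A == floor(A))
    alphabet <- if (A == 4) c("A", "C", "G", "T") else
      c(LETTERS, letters, as.character(0:9))[seq_len(A)]
  } else {
    alphabet <- as.character(alphabet)
    stopifnot(all(nchar(alphabet) == 1L), !anyDuplicated(alphabet))
    A <- length(alphabet)
  }
  structure(list(L = as.integer(L), A = as.integer(A), alphabet = alphabet),
            class = "seq_space")
}

#' @export
print.seq_space <- function(x, ...) {
  cat("<seq_space> L = ", x$L, ", alphabet = {", paste(x$alphabet, collapse = ""),
      "} (A = ", x$A, "), size = ", format(space_size(x)), "\n", sep = "")
  invisible(x)
}

#' Total number of sequences in a space
#'
#' `A^L` as an exact arbitrary-precision integer — never a rounded double.
#'
#' @param space A [seq_space()].
#' @return A `pw_bigint`; coerce with `as.numeric()` (lossy above 2^53) or
#'   `as.character()` (exact).
#' @export
space_size <- function(space) {
  stopifnot(inherits(space, "seq_space"))
  bi_pow_small(space$A, space$L)
}

check_sequence <- function(s, space) {
  stopifnot(is.character(s), length(s) == 1L)
  if (nchar(s) != space$L)
    stop("sequence length ", nchar(s), " != space L = ", space$L)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- setdiff(ch, space$alphabet)
  if (length(bad))
    stop("characters outside alphabet: ", paste(unique(bad), collapse = ", "))
  invisible(ch)
}

# integer encoding 1..A per position, used by the simulators
seq_encode <- function(s, space) {
  ch <- check_sequence(s, space)
  match(ch, space$alphabet)
}

seq_decode <- function(code, space) {
  paste(space$alphabet[code], collapse = "")
}

#' Hamming distance between two sequences
#'
#' @param a,b Character strings of equal length over the same alphabet.
#' @return Integer count of mismatched positions, in `[0, nchar(a)]`.
#' @examples
#' hamming_distance("ACGT", "TGCA")  # 4
#' @export
hamming_distance <- function(a, b) {
  stopifnot(is.character(a), is.character(b), length(a) == length(b))
  if (any(nchar(a) != nchar(b))) stop("sequences must have equal length")
  mapply(function(x, y) {
    sum(strsplit(x, "", fixed = TRUE)[[1]] != strsplit(y, "", fixed = TRUE)[[1]])
  }, a, b, USE.NAMES = FALSE)
}

#' All point-mutation neighbors of a sequence
#'
#' Exactly `L * (A - 1)` sequences at Hamming distance one, in deterministic
#' order: by position, then alphabet order. The ordering is what makes greedy
#' tie-breaking on tabulated landscapes reproducible.
#'
#' @param s A sequence (character string).
#' @param space The [seq_space()] it lives in.
#' @return Character vector of length `L * (A - 1)`.
#' @export
seq_neighbors <- function(s, space) {
  ch <- check_sequence(s, space)
  out <- character(space$L * (space$A - 1L))
  k <- 0L
  for (i in seq_len(space$L)) {
    for (a in space$alphabet) {
      if (a != ch[i]) {
        k <- k + 1L
        mut <- ch
        mut[i] <- a
        out[k] <- paste(mut, collapse = "")
      }
    }
  }
  out
}

#' Propose a uniformly random point mutation
#'
#' Draws one of the `L * (A - 1)` neighbors uniformly at random — the proposal
#' step of the evolutionary random walk. Uses R's RNG; seed with [set.seed()].
#'
#' @inheritParams seq_neighbors
#' @return A single neighboring sequence.
#' @export
propose_mutation <- function(s, space) {
  ch <- check_sequence(s, space)
  i <- sample.int(space$L, 1L)
  others <- space$alphabet[space$alphabet != ch[i]]
  ch[i] <- others[sample.int(space$A - 1L, 1L)]
  paste(ch, collapse = "")
}

#' Draw uniformly random sequences
#'
#' Each position i.i.d. uniform over the alphabet.
#'
#' @param space A [seq_space()].
#' @param n Number of sequences to draw.
#' @return Character vector of length `n`.
#' @export
random_sequence <- function(space, n = 1) {
  vapply(seq_len(n), function(i) {
    paste(sample(space$alphabet, space$L, replace = TRUE), collapse = "")
  }, character(1))
}

#' Draw random sequences at an exact Hamming distance from a center
#'
#' Uniform over the distance-`d` shell: `d` positions chosen without
#' replacement, each assigned a uniformly random non-center letter.
#'
#' @param space A [seq_space()].
#' @param center Center sequence.
#' @param d Required Hamming distance, `0 <= d <= L`.
#' @param n Number of sequences.
#' @return Character vector of length `n`, each at distance exactly `d`.
#' @export
random_sequence_at_distance <- function(space, center, d, n = 1) {
  ch0 <- check_sequence(center, space)
  stopifnot(d >= 0, d <= space$L)
  vapply(seq_len(n), function(i) {
    ch <- ch0
    pos <- sample.int(space$L, d)
    for (p in pos) {
      others <- space$alphabet[space$alphabet != ch0[p]]
      ch[p] <- others[sample.int(space$A - 1L, 1L)]
    }
    paste(ch, collapse = "")
  }, character(1))
}

#' Exact volume of a Hamming ball
#'
#' Number of sequences within Hamming distance `w` of a fixed center:
#' `sum_{i=0}^{w} choose(L, i) * (A - 1)^i`, in exact integer arithmetic.
#' A broad peak of width `w = c * L` contains this many target sequences — an
#' exponential function of `L` for fixed `c > 0`.
#'
#' @param L Sequence length.
#' @param w Ball radius, `0 <= w <= L`.
#' @param A Alphabet size.
#' @return A `pw_bigint` exact integer.
#' @examples
#' as.numeric(ball_volume(4, 1, 4))  # 1 + 4*3 = 13
#' @export
ball_volume <- function(L, w, A = 4) {
  stopifnot(L >= 0, A >= 2, L == floor(L), A == floor(A))
  if (w < 0 || w > L) stop("require 0 <= w <= L, got w = ", w)
  total <- bi(1)              # i = 0 term
  term <- bi(1)               # C(L, i) * (A-1)^i
  i <- 0
  while (i < w) {
    # C(L, i+1) = C(L, i) * (L - i) / (i + 1), times one extra factor (A-1)
    term <- bi_div_small(bi_mul_small(term, (L - i) * (A - 1)), i + 1)
    total <- bi_add(total, term)
    i <- i + 1
  }
  total
}

# log of ball_volume without big-integer work (stable for very large L)
ball_volume_log <- function(L, w, A = 4) {
  if (w < 0 || w > L) stop("require 0 <= w <= L")
  terms <- lchoose(L, 0:w) + (0:w) * log(A - 1)
  m <- max(terms)
  m + log(sum(exp(terms - m)))
}

#' Read target-center sequences from a FASTA file
#'
#' Thin wrapper over `Biostrings::readDNAStringSet()` (or `readBStringSet()`
#' for non-nucleotide alphabets). Characters are uppercased; any character
#' outside the space's alphabet is an error.
#'
#' @param path Path to a single- or multi-record FASTA file.
#' @param space A [seq_space()]; every record must have length `space$L`.
#' @return Named character vector of sequences.
#' @export
read_center_fasta <- function(path, space) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("reading FASTA requires the Biostrings package")
  set <- if (setequal(space$alphabet, c("A", "C", "G", "T")))
    Biostrings::readDNAStringSet(path) else Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  for (s in seqs) check_sequence(s, space)
  seqs
}
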