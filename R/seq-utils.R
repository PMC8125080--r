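# Low-level nucleotide utilities shared by the generator and the detectors.
# Sequences are plain uppercase character scalars (ACGT alphabet); integer
# encodings (A=1 C=2 G=3 T=4) are used in hot loops.

DNA_ALPHABET <- c("A", "C", "G", "T")

.base_lookup <- local({
  lk <- integer(128L)
  lk[utf8ToInt("A")] <- 1L
  lk[utf8ToInt("C")] <- 2L
  lk[utf8ToInt("G")] <- 3L
  lk[utf8ToInt("T")] <- 4L
  lk
})

#' Convert a DNA string to an integer vector (A=1, C=2, G=3, T=4)
#' @param s character scalar over ACGT
#' @return integer vector
#' @keywords internal
seq_to_int <- function(s) {
  .base_lookup[utf8ToInt(s)]
}

#' Convert an integer base vector back to a DNA string
#' @param x integer vector in 1..4
#' @return character scalar
#' @keywords internal
int_to_seq <- function(x) {
  paste(DNA_ALPHABET[x], collapse = "")
}

#' Uniform random DNA string
#' @param n length in bases
#' @return character scalar
#' @export
rand_dna <- function(n) {
  int_to_seq(sample.int(4L, n, replace = TRUE))
}

#' Reverse complement of a DNA string
#' @param s character scalar over ACGT
#' @return character scalar
#' @export
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' All overlapping k-mers of a sequence as strings
#' @param s character scalar
#' @param k word size
#' @return character vector of length nchar(s) - k + 1 (empty if shorter)
#' @keywords internal
kmer_strings <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, seq_len(n - k + 1L), k:n)
}

#' Draw a random Markov transition matrix
#'
#' Rows are contexts (all 4^order words in lexicographic order, last base
#' varying fastest), columns the next-base distribution, sampled from a
#' symmetric Dirichlet. Small concentration values give strongly distinct,
#' "well-separated" compositional signatures across independently drawn
#' chains.
#'
#' @param order Markov order (context length in bases)
#' @param alpha Dirichlet concentration for each transition row
#' @return 4^order x 4 matrix of transition probabilities
#' @export
new_markov_chain <- function(order, alpha = 1) {
  stopifnot(order >= 0, alpha > 0)
  n_ctx <- 4L^order
  g <- matrix(rgamma(n_ctx * 4L, shape = alpha), nrow = n_ctx)
  g / rowSums(g)
}

#' Sample a sequence from a Markov chain
#' @param trans transition matrix from [new_markov_chain()]
#' @param len sequence length in bases
#' @return character scalar
#' @export
markov_generate <- function(trans, len) {
  order <- as.integer(round(log(nrow(trans), 4)))
  stopifnot(4L^order == nrow(trans), len > order)
  cum <- trans
  cum[, 2L] <- cum[, 1L] + cum[, 2L]
  cum[, 3L] <- cum[, 2L] + cum[, 3L]
  x <- integer(len)
  if (order == 0L) {
    u <- runif(len)
    for (i in seq_len(len)) {
      x[i] <- 1L + (u[i] > cum[1L, 1L]) + (u[i] > cum[1L, 2L]) + (u[i] > cum[1L, 3L])
    }
    return(int_to_seq(x))
  }
  x[seq_len(order)] <- sample.int(4L, order, replace = TRUE)
  ctx <- 0L
  for (i in seq_len(order)) ctx <- ctx * 4L + (x[i] - 1L)
  mod <- 4L^(order - 1L)
  u <- runif(len)
  c1 <- cum[, 1L]; c2 <- cum[, 2L]; c3 <- cum[, 3L]
  for (i in (order + 1L):len) {
    r <- ctx + 1L
    b <- 1L + (u[i] > c1[r]) + (u[i] > c2[r]) + (u[i] > c3[r])
    x[i] <- b
    ctx <- (ctx %% mod) * 4L + (b - 1L)
  }
  int_to_seq(x)
}

#' Apply random substitutions to a sequence
#' @param s character scalar
#' @param rate per-base substitution probability (ignored if n_sub given)
#' @param n_sub exact number of substitutions at distinct positions
#' @return character scalar of the same length
#' @export
mutate_seq <- function(s, rate = NULL, n_sub = NULL) {
  x <- seq_to_int(s)
  n <- length(x)
  if (is.null(n_sub)) {
    stopifnot(!is.null(rate), rate >= 0, rate <= 1)
    n_sub <- rbinom(1L, n, rate)
  }
  if (n_sub == 0L) return(s)
  pos <- sample.int(n, n_sub)
  # replace with a uniformly chosen *different* base
  shift <- sample.int(3L, n_sub, replace = TRUE)
  x[pos] <- 1L + (x[pos] - 1L + shift) %% 4L
  int_to_seq(x)
}

#' Insert multiple fragments into a sequence in one pass
#'
#' Positions are 0-based offsets into the *original* sequence (insertion
#' happens before the base at that offset). Returns the modified sequence and
#' the final 0-based half-open coordinates of every inserted fragment.
#'
#' @param s character scalar
#' @param inserts data.frame with columns `pos` (0-based insertion offset)
#'   and `frag` (fragment sequence); extra columns are carried through
#' @return list with `seq` and `coords` (inserts plus `start`, `end`)
#' @keywords internal
apply_insertions <- function(s, inserts) {
  if (nrow(inserts) == 0L) {
    return(list(seq = s, coords = cbind(inserts, start = integer(0), end = integer(0))))
  }
  stopifnot(all(inserts$pos >= 0L), all(inserts$pos <= nchar(s)))
  ord <- order(inserts$pos)
  inserts <- inserts[ord, , drop = FALSE]
  lens <- nchar(inserts$frag)
  pieces <- character(2L * nrow(inserts) + 1L)
  prev <- 0L
  for (i in seq_len(nrow(inserts))) {
    pieces[2L * i - 1L] <- substr(s, prev + 1L, inserts$pos[i])
    pieces[2L * i] <- inserts$frag[i]
    prev <- inserts$pos[i]
  }
  pieces[2L * nrow(inserts) + 1L] <- substr(s, prev + 1L, nchar(s))
  shift <- cumsum(c(0L, lens[-length(lens)]))
  start <- inserts$pos + shift
  coords <- cbind(inserts, start = start, end = start + lens)
  list(seq = paste(pieces, collapse = ""), coords = coords)
}

#' Count identical bases between two raw-encoded sequence windows
#' @keywords internal
.match_count <- function(ra, rb, ia, ib, len) {
  sum(ra[ia:(ia + len - 1L)] == rb[ib:(ib + len - 1L)])
}
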