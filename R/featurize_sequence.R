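# Token encoding of amino-acid sequences for the sequence-based models.
#
# The vocabulary is one symbol per residue: a padding token (index 0), the 20
# canonical amino acids in alphabetical order (indices 1..20), and a single
# unknown symbol X (index 21) that absorbs ambiguous residues (B, Z, U, O and
# anything else non-canonical).

AA_CANONICAL <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_SYMBOLS <- c(AA_CANONICAL, "X")

#' Token vocabulary for amino-acid sequences
#'
#' @return A `pb_vocab`: ordered symbol list (pad first, then the 20 canonical
#'   amino acids alphabetically, then the unknown symbol), with `pad_index` 0
#'   and `unknown_index` 21.
#' @export
token_vocabulary <- function() {
  structure(list(symbols = c("-", AA_CANONICAL, "X"),
                 pad_index = 0L, unknown_index = 21L,
                 n_tokens = 21L),  # real tokens, excluding pad
            class = "pb_vocab")
}

#' Tokenize an amino-acid sequence
#'
#' Maps each residue character to its vocabulary index, truncating to the
#' first `max_length` residues. Long proteins are truncated from the C
#' terminus (the first `max_length` residues are kept); the default cap of
#' 300 bounds recurrent-model memory.
#'
#' @param sequence Non-empty amino-acid string.
#' @param vocab A [token_vocabulary()].
#' @param max_length Truncation length (default 300).
#' @return Integer vector of token indices (1..21; never the pad index).
#' @examples
#' tokenize("ACD")  # 1 2 3
#' @export
tokenize <- function(sequence, vocab = token_vocabulary(), max_length = 300L) {
  if (is.na(sequence) || !nzchar(sequence)) {
    pb_stop("pb_empty_sequence", "cannot tokenize an empty sequence")
  }
  ch <- strsplit(toupper(sequence), "")[[1L]]
  if (length(ch) > max_length) ch <- ch[seq_len(max_length)]
  tok <- match(ch, AA_CANONICAL)
  tok[is.na(tok)] <- vocab$unknown_index
  as.integer(tok)
}

#' Recover a sequence from its tokens
#'
#' Inverse of [tokenize()] for sequences within the truncation limit;
#' unknown tokens render as `X` and pad tokens are dropped.
#'
#' @param tokens Integer token vector.
#' @param vocab A [token_vocabulary()].
#' @return Character string.
#' @export
detokenize <- function(tokens, vocab = token_vocabulary()) {
  tokens <- tokens[tokens != vocab$pad_index]
  paste(vocab$symbols[tokens + 1L], collapse = "")
}

#' Pad token lists into a rectangular batch
#'
#' Rows are padded with the pad index to the longest sequence in the batch;
#' the binary mask is 1 exactly at real residue positions.
#'
#' @param token_lists Non-empty list of non-empty integer token vectors.
#' @param labels Optional per-record label object carried along unchanged.
#' @return A `pb_batch`: `token_matrix` (batch x max length), `mask` (same
#'   shape), `lengths`, and `labels`.
#' @export
pad_and_mask <- function(token_lists, labels = NULL) {
  if (length(token_lists) == 0L) {
    pb_stop("pb_empty_batch", "cannot build a batch from zero sequences")
  }
  lens <- vapply(token_lists, length, integer(1L))
  if (any(lens == 0L)) {
    pb_stop("pb_empty_sequence", "batch contains an empty token list")
  }
  L <- max(lens)
  B <- length(token_lists)
  tm <- matrix(0L, B, L)
  mask <- matrix(0L, B, L)
  for (i in seq_len(B)) {
    tm[i, seq_len(lens[i])] <- token_lists[[i]]
    mask[i, seq_len(lens[i])] <- 1L
  }
  structure(list(token_matrix = tm, mask = mask, lengths = lens,
                 labels = labels),
            class = "pb_batch")
}

#' One-hot encode a batch
#'
#' Every real residue position becomes a unit row over the 21 non-pad
#' vocabulary symbols; pad positions are all-zero, so one-hot row sums
#' reproduce the mask.
#'
#' @param batch A `pb_batch` from [pad_and_mask()].
#' @param vocab A [token_vocabulary()].
#' @return Numeric array of dim (batch, length, 21).
#' @export
one_hot <- function(batch, vocab = token_vocabulary()) {
  stopifnot(inherits(batch, "pb_batch"))
  tm <- batch$token_matrix
  out <- array(0, dim = c(nrow(tm), ncol(tm), vocab$n_tokens))
  real <- which(tm != vocab$pad_index, arr.ind = TRUE)
  out[cbind(real, tm[real])] <- 1
  out
}

# Flattened (B*L) x 21 one-hot matrix with rows ordered position-fastest
# within each sequence — the layout the sequence models consume.
one_hot_flat <- function(batch, vocab = token_vocabulary()) {
  tm <- batch$token_matrix
  B <- nrow(tm); L <- ncol(tm)
  tok <- as.integer(t(tm))             # row (i-1)*L + l  <-> sample i, pos l
  out <- matrix(0, B * L, vocab$n_tokens)
  real <- which(tok != vocab$pad_index)
  out[cbind(real, tok[real])] <- 1
  out
}
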