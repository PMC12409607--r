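## SMILES tokenization, vocabulary handling and one-hot encoding.

## Single-character tokens the tokenizer accepts outside brackets.
.SINGLE_TOKENS <- c("C", "O", "N", "S", "P", "F", "I",
                    "c", "n", "o", "s", "p",
                    as.character(1:9),
                    "(", ")", "-", "=", "#", "/", "\\", "*", ".")

#' Tokenize SMILES strings
#'
#' Splits a SMILES string into lexical tokens: two-character halogens
#' (`Cl`, `Br`) and bracket atom expressions (`[nH]`, `[N+]`, ...) are
#' single tokens, `%NN` two-digit ring closures are single tokens, and the
#' mask atom surface forms `*` and `[*]` both map to the single token `*`.
#' Optionally frames the sequence with the begin marker `G` and end marker
#' `E`.
#'
#' @param smiles Character vector of SMILES strings.
#' @param with_markers Prepend `G` and append `E` to each sequence.
#' @return A list of character token vectors, one per input string.
#' @examples
#' tokenizeSmiles("c1ccc(Cl)cc1")[[1]]
#' tokenizeSmiles("CCO", with_markers = TRUE)[[1]]
#' @export
tokenizeSmiles <- function(smiles, with_markers = FALSE) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  lapply(smiles, .tokenizeOne, with_markers = with_markers)
}

.tokenizeOne <- function(s, with_markers = FALSE) {
  if (is.na(s) || !nzchar(s)) {
    stop("cannot tokenize an empty SMILES string", call. = FALSE)
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  tokens <- character(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) {
        stop("unclosed bracket expression at position ", i, " in '", s, "'",
             call. = FALSE)
      }
      tok <- paste(chars[i:j], collapse = "")
      if (tok == "[*]") tok <- "*"
      tokens <- c(tokens, tok)
      i <- j + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !all(grepl("[0-9]", chars[(i + 1L):(i + 2L)]))) {
        stop("malformed '%NN' ring closure at position ", i, " in '", s, "'",
             call. = FALSE)
      }
      tokens <- c(tokens, paste(chars[i:(i + 2L)], collapse = ""))
      i <- i + 3L
    } else if (ch == "C" && i < n && chars[i + 1L] == "l") {
      tokens <- c(tokens, "Cl")
      i <- i + 2L
    } else if (ch == "B" && i < n && chars[i + 1L] == "r") {
      tokens <- c(tokens, "Br")
      i <- i + 2L
    } else if (ch %in% .SINGLE_TOKENS) {
      tokens <- c(tokens, ch)
      i <- i + 1L
    } else {
      stop("unrecognized character '", ch, "' at position ", i, " in '", s,
           "'", call. = FALSE)
    }
  }
  if (with_markers) tokens <- c("G", tokens, "E")
  tokens
}

#' Reassemble a token sequence into a SMILES string
#'
#' The exact inverse of [tokenizeSmiles()]: concatenates tokens, dropping
#' `G`/`E` markers and padding tokens if present.
#'
#' @param tokens A character token vector, or a list of them.
#' @return A character vector of SMILES strings.
#' @examples
#' detokenizeSmiles(tokenizeSmiles("c1ccc(Cl)cc1"))
#' @export
detokenizeSmiles <- function(tokens) {
  if (!is.list(tokens)) tokens <- list(tokens)
  vapply(tokens, function(tk) {
    tk <- tk[!tk %in% c("G", "E", "<pad>")]
    paste(tk, collapse = "")
  }, character(1))
}

#' Build a SMILES vocabulary
#'
#' Collects the distinct tokens of a corpus and assigns contiguous 0-based
#' indices.  The four special tokens (`<pad>`, `G`, `E`, `*`) are always
#' present and occupy the first indices.
#'
#' @param sequences A list of token vectors (as returned by
#'   [tokenizeSmiles()]), or a character vector of SMILES strings which are
#'   tokenized first.
#' @return A [SmilesVocabulary-class] object.
#' @examples
#' vocab <- smilesVocabulary(c("CCO", "c1ccccc1"))
#' vocabTokens(vocab)
#' @export
smilesVocabulary <- function(sequences) {
  if (is.character(sequences)) sequences <- tokenizeSmiles(sequences)
  specials <- c("<pad>", "G", "E", "*")
  data_tokens <- sort(setdiff(unique(unlist(sequences)), specials))
  new("SmilesVocabulary", tokens = c(specials, data_tokens))
}

#' @describeIn smilesVocabulary Tokens in index order (index 0 first).
#' @param vocab A [SmilesVocabulary-class].
#' @export
vocabTokens <- function(vocab) {
  stopifnot(is(vocab, "SmilesVocabulary"))
  vocab@tokens
}

#' @describeIn smilesVocabulary Number of tokens in the vocabulary.
#' @export
vocabSize <- function(vocab) {
  stopifnot(is(vocab, "SmilesVocabulary"))
  length(vocab@tokens)
}

## 1-based positions of tokens in the vocabulary; errors on unknown tokens.
.tokenPositions <- function(tokens, vocab) {
  idx <- match(tokens, vocab@tokens)
  if (anyNA(idx)) {
    stop("token(s) not in vocabulary: ",
         paste(unique(tokens[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  idx
}

#' Serialize a vocabulary as JSON
#'
#' Writes the vocabulary as a JSON object mapping each token to its 0-based
#' index; [readVocabulary()] is the inverse.
#'
#' @param vocab A [SmilesVocabulary-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeVocabulary <- function(vocab, path) {
  stopifnot(is(vocab, "SmilesVocabulary"))
  x <- as.list(setNames(seq_along(vocab@tokens) - 1L, vocab@tokens))
  jsonlite::write_json(x, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeVocabulary
#' @export
readVocabulary <- function(path) {
  x <- jsonlite::fromJSON(path)
  idx <- unlist(x)
  new("SmilesVocabulary", tokens = names(sort(idx)))
}

#' One-hot encode token sequences
#'
#' Encodes a list of token sequences as an `n x max_len x V` array in which
#' each position along the second axis is either the unit basis vector of a
#' token or the basis vector of the padding token.
#'
#' @param sequences List of character token vectors.
#' @param vocab A [SmilesVocabulary-class].
#' @param max_len Maximum sequence length after markers; longer sequences
#'   are an error (filter upstream, never truncate).
#' @return A numeric array of dim `c(length(sequences), max_len,
#'   vocabSize(vocab))`.
#' @examples
#' vocab <- smilesVocabulary(c("CCO"))
#' x <- encodeSequences(tokenizeSmiles("CCO", with_markers = TRUE), vocab, 6)
#' dim(x)
#' @export
encodeSequences <- function(sequences, vocab, max_len = 150L) {
  stopifnot(is.list(sequences), is(vocab, "SmilesVocabulary"))
  lens <- lengths(sequences)
  if (any(lens > max_len)) {
    stop(sum(lens > max_len), " sequence(s) exceed max_len = ", max_len,
         "; filter over-length sequences before encoding", call. = FALSE)
  }
  V <- vocabSize(vocab)
  pad <- .tokenPositions("<pad>", vocab)
  out <- array(0, dim = c(length(sequences), max_len, V))
  for (i in seq_along(sequences)) {
    pos <- c(.tokenPositions(sequences[[i]], vocab),
             rep(pad, max_len - lens[i]))
    out[cbind(i, seq_len(max_len), pos)] <- 1
  }
  out
}

#' @rdname encodeSequences
#' @param x An array produced by `encodeSequences()`.
#' @return `decodeSequences()` returns the list of token vectors with
#'   padding removed.
#' @export
decodeSequences <- function(x, vocab) {
  stopifnot(is.array(x), length(dim(x)) == 3L, is(vocab, "SmilesVocabulary"))
  toks <- vocab@tokens
  lapply(seq_len(dim(x)[1]), function(i) {
    idx <- apply(x[i, , , drop = FALSE], 2, which.max)
    out <- toks[idx]
    out[out != "<pad>"]
  })
}
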