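#' Clean free-text labels into canonical lemmas
#'
#' Normalizes raw crowd labels through a fixed chain: lowercasing,
#' transliteration to the closest ASCII, removal of non-alphabetic
#' characters, abbreviation expansion, whitespace stripping, dictionary-based
#' word segmentation (dynamic programming over the lexicon), tokenization,
#' retention of nouns/adjectives/prepositions only, spell correction (edit
#' distance at most 2 against the lexicon), and lemmatization (lexicon lookup
#' plus regular-plural stripping). Tokens whose lemma does not exist in the
#' lexicon become the sentinel `"unknown"`; an entry that cleans to nothing
#' also becomes `"unknown"`.
#'
#' The lexicon is a compact word/part-of-speech/lemma table shipped with the
#' package (`inst/extdata/lexicon.csv`) and user-extensible via
#' `extra_words`.
#'
#' @param A Character vector, matrix or data frame of raw labels; `NA`
#'   entries stay `NA` (subject did not see the image).
#' @param lexicon Lexicon data frame (`word`, `pos`, `lemma`); defaults to
#'   the shipped one.
#' @param abbreviations Named character vector, abbreviation -> expansion.
#' @param extra_words Optional data frame with the lexicon columns, appended
#'   to the lexicon (e.g. study-specific category names).
#' @return Object of the same shape as `A` with cleaned entries.
#' @export
#' @examples
#' clean_labels(c("  MUSHROOMS ", "Cockatoo!!", "zxqvvb"))
clean_labels <- function(A, lexicon = default_lexicon(),
                         abbreviations = default_abbreviations(),
                         extra_words = NULL) {
  if (!is.null(extra_words)) {
    stopifnot(all(c("word", "pos", "lemma") %in% names(extra_words)))
    lexicon <- rbind(lexicon, extra_words[, c("word", "pos", "lemma")])
    lexicon <- lexicon[!duplicated(lexicon$word), ]
  }
  raw <- if (is.data.frame(A)) as.matrix(A) else A
  vals <- as.character(raw)
  uniq <- unique(vals[!is.na(vals)])
  cleaned <- vapply(uniq, clean_label_string, character(1),
                    lexicon = lexicon, abbreviations = abbreviations)
  out <- vals
  out[!is.na(vals)] <- cleaned[match(vals[!is.na(vals)], uniq)]
  if (is.matrix(raw)) {
    out <- matrix(out, nrow(raw), ncol(raw), dimnames = dimnames(raw))
  }
  out
}

#' @rdname clean_labels
#' @export
unknown_sentinel <- function() "unknown"

clean_label_string <- function(s, lexicon, abbreviations) {
  s <- tolower(s)
  s <- iconv(s, from = "", to = "ASCII//TRANSLIT", sub = "")
  if (is.na(s)) s <- ""
  s <- gsub("[^a-z]+", " ", s)
  toks <- strsplit(trimws(s), "\\s+")[[1L]]
  toks <- toks[nzchar(toks)]
  expanded <- unlist(lapply(toks, function(t) {
    if (t %in% names(abbreviations)) abbreviations[[t]] else t
  }), use.names = FALSE)
  segmented <- unlist(lapply(expanded, segment_word, lexicon = lexicon),
                      use.names = FALSE)
  lemmas <- character(0)
  for (t in segmented) {
    hit <- lexicon_resolve(t, lexicon)
    if (is.null(hit)) {
      corrected <- spell_correct(t, lexicon)
      hit <- if (is.null(corrected)) NULL else lexicon_resolve(corrected, lexicon)
    }
    if (is.null(hit)) {
      lemmas <- c(lemmas, unknown_sentinel())
    } else if (hit$pos %in% c("noun", "adj", "prep")) {
      lemmas <- c(lemmas, hit$lemma)
    }
    # other parts of speech (verbs, determiners, ...) are dropped
  }
  lemmas <- lemmas[!(duplicated(lemmas) & lemmas == unknown_sentinel())]
  if (length(lemmas) == 0L) return(unknown_sentinel())
  paste(lemmas, collapse = " ")
}

# direct or regular-plural lexicon lookup; NULL when absent
lexicon_resolve <- function(w, lexicon) {
  i <- match(w, lexicon$word)
  if (!is.na(i)) return(list(lemma = lexicon$lemma[[i]], pos = lexicon$pos[[i]]))
  for (base in plural_candidates(w)) {
    i <- match(base, lexicon$word)
    if (!is.na(i) && lexicon$pos[[i]] == "noun") {
      return(list(lemma = lexicon$lemma[[i]], pos = "noun"))
    }
  }
  NULL
}

plural_candidates <- function(w) {
  out <- character(0)
  if (grepl("ies$", w) && nchar(w) > 4) out <- c(out, sub("ies$", "y", w))
  if (grepl("ves$", w)) out <- c(out, sub("ves$", "f", w), sub("ves$", "fe", w))
  if (grepl("(s|x|z|ch|sh)es$", w)) out <- c(out, sub("es$", "", w))
  if (grepl("s$", w) && !grepl("ss$", w)) out <- c(out, sub("s$", "", w))
  unique(out)
}

# SymSpell-flavoured dictionary segmentation: split an unspaced token into
# known words (fewest pieces, then longest-first), each piece >= 2 chars.
# Returns the token unchanged when it is already known or unsegmentable.
segment_word <- function(w, lexicon) {
  if (!is.null(lexicon_resolve(w, lexicon)) || nchar(w) < 4) return(w)
  n <- nchar(w)
  # best[i]: fewest pieces covering w[1..i]; back[i]: start of last piece
  best <- c(0, rep.int(Inf, n))
  back <- integer(n + 1L)
  for (i in 3:(n + 1L)) {
    for (j in seq_len(i - 2L)) {
      if (!is.finite(best[[j]])) next
      piece <- substr(w, j, i - 1L)
      if (nchar(piece) >= 2 && !is.null(lexicon_resolve(piece, lexicon))) {
        if (best[[j]] + 1 < best[[i]]) {
          best[[i]] <- best[[j]] + 1
          back[[i]] <- j
        }
      }
    }
  }
  if (!is.finite(best[[n + 1L]])) return(w)
  pieces <- character(0)
  i <- n + 1L
  while (i > 1L) {
    j <- back[[i]]
    pieces <- c(substr(w, j, i - 1L), pieces)
    i <- j
  }
  pieces
}

# nearest lexicon word within edit distance 2 (1 for words of <= 4 letters,
# where distance 2 overcorrects); ties resolved by smaller distance then
# lexicographic order; NULL when nothing is close enough
spell_correct <- function(w, lexicon) {
  max_d <- if (nchar(w) <= 4L) 1L else 2L
  words <- lexicon$word
  cand <- words[abs(nchar(words) - nchar(w)) <= max_d]
  if (length(cand) == 0L) return(NULL)
  d <- utils::adist(w, cand)[1L, ]
  dmin <- min(d)
  if (dmin > max_d) return(NULL)
  sort(cand[d == dmin])[[1L]]
}

#' @rdname clean_labels
#' @export
default_lexicon <- function() {
  env <- lexicon_cache
  if (is.null(env$lexicon)) {
    path <- system.file("extdata", "lexicon.csv", package = "crtkit",
                        mustWork = TRUE)
    env$lexicon <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  env$lexicon
}

lexicon_cache <- new.env(parent = emptyenv())

#' @rdname clean_labels
#' @export
default_abbreviations <- function() {
  c(veg = "vegetable", lib = "library", pic = "picture", mt = "mountain",
    choc = "chocolate", bbq = "barbecue")
}
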