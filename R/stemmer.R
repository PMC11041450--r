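# Porter (1980) suffix-stripping stemmer, implemented here because no
# stemming library ships with the package's dependency set. Operates on
# lower-case ASCII words; words of length <= 2 are returned unchanged.

porter_is_cons <- function(chars, i) {
  ch <- chars[i]
  if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (ch == "y") {
    if (i == 1L) return(TRUE)
    return(!porter_is_cons(chars, i - 1L))
  }
  TRUE
}

porter_measure <- function(chars) {
  n <- length(chars)
  if (n == 0L) return(0L)
  types <- vapply(seq_len(n), function(i) porter_is_cons(chars, i), logical(1))
  m <- 0L
  prev_vowel <- FALSE
  for (i in seq_len(n)) {
    if (types[i] && prev_vowel) m <- m + 1L
    prev_vowel <- !types[i]
  }
  m
}

porter_has_vowel <- function(chars) {
  any(!vapply(seq_along(chars), function(i) porter_is_cons(chars, i),
              logical(1)))
}

porter_double_cons <- function(chars) {
  n <- length(chars)
  n >= 2L && chars[n] == chars[n - 1L] && porter_is_cons(chars, n)
}

porter_cvc <- function(chars) {
  n <- length(chars)
  if (n < 3L) return(FALSE)
  porter_is_cons(chars, n - 2L) && !porter_is_cons(chars, n - 1L) &&
    porter_is_cons(chars, n) && !(chars[n] %in% c("w", "x", "y"))
}

porter_ends <- function(word, suffix) {
  nchar(word) > nchar(suffix) &&
    substring(word, nchar(word) - nchar(suffix) + 1L) == suffix
}

porter_chop <- function(word, suffix) {
  substr(word, 1L, nchar(word) - nchar(suffix))
}

porter_stem_one <- function(word) {
  if (nchar(word) <= 2L) return(word)
  chars_of <- function(w) strsplit(w, "", fixed = TRUE)[[1]]

  # step 1a
  if (porter_ends(word, "sses")) {
    word <- paste0(porter_chop(word, "sses"), "ss")
  } else if (porter_ends(word, "ies")) {
    word <- paste0(porter_chop(word, "ies"), "i")
  } else if (!porter_ends(word, "ss") && porter_ends(word, "s")) {
    word <- porter_chop(word, "s")
  }

  # step 1b
  flag1b <- FALSE
  if (porter_ends(word, "eed")) {
    stem <- porter_chop(word, "eed")
    if (porter_measure(chars_of(stem)) > 0L) word <- paste0(stem, "ee")
  } else if (porter_ends(word, "ed")) {
    stem <- porter_chop(word, "ed")
    if (porter_has_vowel(chars_of(stem))) { word <- stem; flag1b <- TRUE }
  } else if (porter_ends(word, "ing")) {
    stem <- porter_chop(word, "ing")
    if (porter_has_vowel(chars_of(stem))) { word <- stem; flag1b <- TRUE }
  }
  if (flag1b) {
    if (porter_ends(word, "at") || porter_ends(word, "bl") ||
        porter_ends(word, "iz")) {
      word <- paste0(word, "e")
    } else {
      ch <- chars_of(word)
      if (porter_double_cons(ch) && !(ch[length(ch)] %in% c("l", "s", "z"))) {
        word <- substr(word, 1L, nchar(word) - 1L)
      } else if (porter_measure(ch) == 1L && porter_cvc(ch)) {
        word <- paste0(word, "e")
      }
    }
  }

  # step 1c
  if (porter_ends(word, "y")) {
    stem <- porter_chop(word, "y")
    if (porter_has_vowel(chars_of(stem))) word <- paste0(stem, "i")
  }

  apply_map <- function(word, rules, min_m) {
    for (k in seq_len(nrow(rules))) {
      suf <- rules$from[k]
      if (porter_ends(word, suf)) {
        stem <- porter_chop(word, suf)
        if (porter_measure(chars_of(stem)) > min_m - 1L) {
          return(paste0(stem, rules$to[k]))
        }
        return(word)
      }
    }
    word
  }

  step2 <- data.frame(
    from = c("ational", "tional", "enci", "anci", "izer", "abli", "alli",
             "entli", "eli", "ousli", "ization", "ation", "ator", "alism",
             "iveness", "fulness", "ousness", "aliti", "iviti", "biliti"),
    to = c("ate", "tion", "ence", "ance", "ize", "able", "al", "ent", "e",
           "ous", "ize", "ate", "ate", "al", "ive", "ful", "ous", "al",
           "ive", "ble"),
    stringsAsFactors = FALSE)
  word <- apply_map(word, step2, 1L)

  step3 <- data.frame(
    from = c("icate", "ative", "alize", "iciti", "ical", "ful", "ness"),
    to = c("ic", "", "al", "ic", "ic", "", ""),
    stringsAsFactors = FALSE)
  word <- apply_map(word, step3, 1L)

  # step 4: delete at measure > 1
  step4 <- c("al", "ance", "ence", "er", "ic", "able", "ible", "ant",
             "ement", "ment", "ent", "ion", "ou", "ism", "ate", "iti",
             "ous", "ive", "ize")
  for (suf in step4) {
    if (porter_ends(word, suf)) {
      stem <- porter_chop(word, suf)
      if (porter_measure(chars_of(stem)) > 1L) {
        if (suf == "ion" &&
            !(substring(stem, nchar(stem)) %in% c("s", "t"))) break
        word <- stem
      }
      break
    }
  }

  # step 5a
  if (porter_ends(word, "e")) {
    stem <- porter_chop(word, "e")
    ch <- chars_of(stem)
    m <- porter_measure(ch)
    if (m > 1L || (m == 1L && !porter_cvc(ch))) word <- stem
  }
  # step 5b
  ch <- chars_of(word)
  if (porter_measure(ch) > 1L && porter_double_cons(ch) &&
      ch[length(ch)] == "l") {
    word <- substr(word, 1L, nchar(word) - 1L)
  }
  word
}

#' Stem words with the Porter algorithm
#'
#' @param words character vector of lower-case words.
#' @return character vector of stems.
#' @export
#' @examples
#' porter_stem(c("effects", "running", "adjustable", "relational"))
porter_stem <- function(words) {
  if (!length(words)) return(character(0))
  u <- unique(words)
  stems <- vapply(u, porter_stem_one, character(1), USE.NAMES = FALSE)
  stems[match(words, u)]
}

# Small rule-based noun lemmatizer applied before stemming: maps common
# irregular plurals and regular plural inflections to the singular. Verb
# inflections are left to the stemmer.
lemma_irregular <- c(
  men = "man", women = "woman", children = "child", feet = "foot",
  teeth = "tooth", mice = "mouse", people = "person", analyses = "analysis",
  crises = "crisis", diagnoses = "diagnosis", data = "datum"
)

#' Lemmatize words (plural nouns to singular)
#'
#' @param words character vector of lower-case words.
#' @return character vector of lemmas.
#' @export
lemmatize <- function(words) {
  if (!length(words)) return(character(0))
  out <- words
  irr <- match(words, names(lemma_irregular))
  out[!is.na(irr)] <- lemma_irregular[irr[!is.na(irr)]]
  reg <- is.na(irr)
  w <- out[reg]
  w <- ifelse(grepl("ies$", w) & nchar(w) > 4L, sub("ies$", "y", w), w)
  w <- ifelse(grepl("(ches|shes|sses|xes|zes)$", w), sub("es$", "", w), w)
  w <- ifelse(grepl("[^su]s$", w) & !grepl("(ss|us|is)$", w),
              sub("s$", "", w), w)
  out[reg] <- w
  out
}
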