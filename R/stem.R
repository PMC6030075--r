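#' Porter stemming
#'
#' Classic Porter (1980) suffix-stripping stemmer. The pipeline uses one
#' stemmer everywhere (condenser, dictionary stem index) so that stages agree
#' on what counts as a shared root.
#'
#' @param words character vector of lowercase tokens.
#' @return character vector of stems, same length and order.
#' @examples
#' porter_stem(c("lesions", "probable", "metastasis"))
#' @export
porter_stem <- function(words) {
  if (length(words) == 0L) return(character(0))
  uniq <- unique(words)
  stems <- vapply(uniq, porter_stem1, character(1), USE.NAMES = FALSE)
  stems[match(words, uniq)]
}

# single-word Porter stemmer; words of length <= 2 are left unchanged
porter_stem1 <- function(w) {
  if (is.na(w) || nchar(w) <= 2L) return(w)
  if (grepl("[^a-z]", w)) return(w)  # mixed tokens (digits, '_') pass through

  w <- p_step1a(w)
  w <- p_step1b(w)
  w <- p_step1c(w)
  w <- p_step2(w)
  w <- p_step3(w)
  w <- p_step4(w)
  w <- p_step5(w)
  w
}

# consonant/vowel pattern: TRUE where consonant. 'y' is a consonant at the
# start or after a vowel, a vowel after a consonant.
p_cons <- function(chars) {
  n <- length(chars)
  cons <- !(chars %in% c("a", "e", "i", "o", "u"))
  for (i in seq_len(n)) {
    if (chars[i] == "y") {
      cons[i] <- if (i == 1L) TRUE else !cons[i - 1L]
    }
  }
  cons
}

# m: number of VC sequences in the stem
p_measure <- function(stem) {
  if (nchar(stem) == 0L) return(0L)
  cons <- p_cons(strsplit(stem, "", fixed = TRUE)[[1]])
  # collapse runs, count V->C transitions
  runs <- rle(cons)$values
  sum(runs[-1] == TRUE & runs[-length(runs)] == FALSE)
}

p_has_vowel <- function(stem) {
  if (nchar(stem) == 0L) return(FALSE)
  any(!p_cons(strsplit(stem, "", fixed = TRUE)[[1]]))
}

# *d: ends with a double consonant
p_double_cons <- function(w) {
  n <- nchar(w)
  if (n < 2L) return(FALSE)
  a <- substr(w, n - 1L, n - 1L); b <- substr(w, n, n)
  if (a != b) return(FALSE)
  cons <- p_cons(strsplit(w, "", fixed = TRUE)[[1]])
  cons[n]
}

# *o: ends cvc where the final c is not w, x or y
p_cvc <- function(w) {
  n <- nchar(w)
  if (n < 3L) return(FALSE)
  cons <- p_cons(strsplit(w, "", fixed = TRUE)[[1]])
  if (!(cons[n - 2L] && !cons[n - 1L] && cons[n])) return(FALSE)
  !(substr(w, n, n) %in% c("w", "x", "y"))
}

p_ends <- function(w, suf) {
  n <- nchar(w); s <- nchar(suf)
  n > s && substr(w, n - s + 1L, n) == suf
}

p_step1a <- function(w) {
  if (p_ends(w, "sses")) return(sub("sses$", "ss", w))
  if (p_ends(w, "ies"))  return(sub("ies$", "i", w))
  if (p_ends(w, "ss"))   return(w)
  if (grepl("s$", w))    return(sub("s$", "", w))
  w
}

p_step1b <- function(w) {
  if (p_ends(w, "eed")) {
    stem <- sub("eed$", "", w)
    if (p_measure(stem) > 0L) return(paste0(stem, "ee"))
    return(w)
  }
  fired <- FALSE
  if (p_ends(w, "ed")) {
    stem <- sub("ed$", "", w)
    if (p_has_vowel(stem)) { w <- stem; fired <- TRUE }
  } else if (p_ends(w, "ing")) {
    stem <- sub("ing$", "", w)
    if (p_has_vowel(stem)) { w <- stem; fired <- TRUE }
  }
  if (fired) {
    if (p_ends(w, "at") || p_ends(w, "bl") || p_ends(w, "iz")) return(paste0(w, "e"))
    if (p_double_cons(w) && !(substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z")))
      return(substr(w, 1L, nchar(w) - 1L))
    if (p_measure(w) == 1L && p_cvc(w)) return(paste0(w, "e"))
  }
  w
}

p_step1c <- function(w) {
  if (grepl("y$", w)) {
    stem <- sub("y$", "", w)
    if (p_has_vowel(stem)) return(paste0(stem, "i"))
  }
  w
}

p_rules2 <- list(
  c("ational", "ate"), c("tional", "tion"), c("enci", "ence"), c("anci", "ance"),
  c("izer", "ize"), c("abli", "able"), c("alli", "al"), c("entli", "ent"),
  c("eli", "e"), c("ousli", "ous"), c("ization", "ize"), c("ation", "ate"),
  c("ator", "ate"), c("alism", "al"), c("iveness", "ive"), c("fulness", "ful"),
  c("ousness", "ous"), c("aliti", "al"), c("iviti", "ive"), c("biliti", "ble")
)

p_rules3 <- list(
  c("icate", "ic"), c("ative", ""), c("alize", "al"), c("iciti", "ic"),
  c("ical", "ic"), c("ful", ""), c("ness", "")
)

p_apply_rules <- function(w, rules, min_m) {
  for (r in rules) {
    if (p_ends(w, r[1])) {
      stem <- substr(w, 1L, nchar(w) - nchar(r[1]))
      if (p_measure(stem) > min_m - 1L) return(paste0(stem, r[2]))
      return(w)  # longest matching suffix decides, fire or not
    }
  }
  w
}

p_step2 <- function(w) p_apply_rules(w, p_rules2, 1L)
p_step3 <- function(w) p_apply_rules(w, p_rules3, 1L)

p_step4 <- function(w) {
  sufs <- c("al", "ance", "ence", "er", "ic", "able", "ible", "ant", "ement",
            "ment", "ent", "ion", "ou", "ism", "ate", "iti", "ous", "ive", "ize")
  # match the longest applicable suffix first
  sufs <- sufs[order(nchar(sufs), decreasing = TRUE)]
  for (s in sufs) {
    if (p_ends(w, s)) {
      stem <- substr(w, 1L, nchar(w) - nchar(s))
      if (s == "ion" && !grepl("[st]$", stem)) return(w)
      if (p_measure(stem) > 1L) return(stem)
      return(w)
    }
  }
  w
}

p_step5 <- function(w) {
  # 5a
  if (grepl("e$", w)) {
    stem <- sub("e$", "", w)
    m <- p_measure(stem)
    if (m > 1L || (m == 1L && !p_cvc(stem))) w <- stem
  }
  # 5b
  if (p_measure(w) > 1L && p_double_cons(w) && grepl("l$", w))
    w <- substr(w, 1L, nchar(w) - 1L)
  w
}
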