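#' Word stemmers
#'
#' Root lookup succeeds more often on stemmed forms: a lexicon may hold
#' \emph{gastrointestine} but not \emph{gastrointestinal}; both reduce
#' to the common stem \emph{gastrointestin}.  The package ships a Porter
#' stemmer for English and a Snowball-style stemmer for Spanish.  A
#' stemmer is any pure `character -> character` function; a custom one
#' can be supplied through [parser_config()].
#'
#' @param words character vector of lowercase words.
#' @return character vector of stems, same length as `words`.
#' @examples
#' porter_stem(c("gastrointestinal", "gastrointestine"))
#' spanish_stem(c("enfermedades", "corriendo"))
#' @name stemmers
NULL

# ---- English: Porter (1980) ---------------------------------------------

# consonant test: not aeiou; 'y' is a consonant unless preceded by one
p_cons <- function(ch, i) {
  c0 <- ch[i]
  if (c0 %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (c0 == "y") {
    if (i == 1L) return(TRUE)
    return(!p_cons(ch, i - 1L))
  }
  TRUE
}

# measure m: number of vowel-consonant sequences in the stem
p_measure <- function(stem) {
  if (!nzchar(stem)) return(0L)
  ch <- strsplit(stem, "", fixed = TRUE)[[1]]
  types <- vapply(seq_along(ch), function(i) p_cons(ch, i), logical(1))
  rle_t <- rle(types)
  v <- rle_t$values
  # count V followed by C
  sum(v[-length(v)] == FALSE & v[-1] == TRUE)
}

p_has_vowel <- function(stem) {
  if (!nzchar(stem)) return(FALSE)
  ch <- strsplit(stem, "", fixed = TRUE)[[1]]
  any(!vapply(seq_along(ch), function(i) p_cons(ch, i), logical(1)))
}

p_double_cons <- function(word) {
  n <- nchar(word)
  if (n < 2) return(FALSE)
  a <- substr(word, n - 1, n - 1)
  b <- substr(word, n, n)
  if (a != b) return(FALSE)
  ch <- strsplit(word, "", fixed = TRUE)[[1]]
  p_cons(ch, n)
}

# *o: stem ends cvc where final c is not w, x or y
p_cvc <- function(word) {
  n <- nchar(word)
  if (n < 3) return(FALSE)
  ch <- strsplit(word, "", fixed = TRUE)[[1]]
  if (!p_cons(ch, n) || p_cons(ch, n - 1L) || !p_cons(ch, n - 2L)) return(FALSE)
  !ch[n] %in% c("w", "x", "y")
}

p_ends <- function(word, suffix) {
  n <- nchar(word); k <- nchar(suffix)
  n >= k && substr(word, n - k + 1, n) == suffix
}

p_chop <- function(word, suffix) substr(word, 1, nchar(word) - nchar(suffix))

# try a rule table: list of c(suffix, replacement); condition on stem measure
p_rule <- function(word, rules, min_m = 1L) {
  for (r in rules) {
    if (p_ends(word, r[[1]])) {
      stem <- p_chop(word, r[[1]])
      if (p_measure(stem) >= min_m) return(paste0(stem, r[[2]]))
      return(word)
    }
  }
  word
}

porter_stem_one <- function(word) {
  if (nchar(word) <= 2) return(word)

  # step 1a
  if (p_ends(word, "sses")) word <- p_chop(word, "es")
  else if (p_ends(word, "ies")) word <- p_chop(word, "es")
  else if (!p_ends(word, "ss") && p_ends(word, "s")) word <- p_chop(word, "s")

  # step 1b
  fixup <- FALSE
  if (p_ends(word, "eed")) {
    if (p_measure(p_chop(word, "eed")) > 0) word <- p_chop(word, "d")
  } else if (p_ends(word, "ed") && p_has_vowel(p_chop(word, "ed"))) {
    word <- p_chop(word, "ed"); fixup <- TRUE
  } else if (p_ends(word, "ing") && p_has_vowel(p_chop(word, "ing"))) {
    word <- p_chop(word, "ing"); fixup <- TRUE
  }
  if (fixup) {
    if (p_ends(word, "at") || p_ends(word, "bl") || p_ends(word, "iz")) {
      word <- paste0(word, "e")
    } else if (p_double_cons(word) &&
               !substr(word, nchar(word), nchar(word)) %in% c("l", "s", "z")) {
      word <- substr(word, 1, nchar(word) - 1)
    } else if (p_measure(word) == 1 && p_cvc(word)) {
      word <- paste0(word, "e")
    }
  }

  # step 1c
  if (p_ends(word, "y") && p_has_vowel(p_chop(word, "y"))) {
    word <- paste0(p_chop(word, "y"), "i")
  }

  # step 2 (longest-first within the table)
  word <- p_rule(word, list(
    list("ational", "ate"), list("ization", "ize"), list("iveness", "ive"),
    list("fulness", "ful"), list("ousness", "ous"), list("tional", "tion"),
    list("biliti", "ble"), list("ation", "ate"), list("alism", "al"),
    list("aliti", "al"), list("iviti", "ive"), list("ousli", "ous"),
    list("entli", "ent"), list("enci", "ence"), list("anci", "ance"),
    list("izer", "ize"), list("abli", "able"), list("alli", "al"),
    list("ator", "ate"), list("eli", "e")))

  # step 3
  word <- p_rule(word, list(
    list("icate", "ic"), list("ative", ""), list("alize", "al"),
    list("iciti", "ic"), list("ical", "ic"), list("ness", ""),
    list("ful", "")))

  # step 4: bare deletions at m > 1
  step4 <- c("ement", "ance", "ence", "able", "ible", "ment", "ant", "ent",
             "ism", "ate", "iti", "ous", "ive", "ize", "ion", "al", "er",
             "ic", "ou")
  for (s in step4) {
    if (p_ends(word, s)) {
      stem <- p_chop(word, s)
      ok <- p_measure(stem) > 1
      if (s == "ion") ok <- ok && (p_ends(stem, "s") || p_ends(stem, "t"))
      if (ok) word <- stem
      break
    }
  }

  # step 5a
  if (p_ends(word, "e")) {
    stem <- p_chop(word, "e")
    m <- p_measure(stem)
    if (m > 1 || (m == 1 && !p_cvc(stem))) word <- stem
  }
  # step 5b
  if (p_measure(word) > 1 && p_double_cons(word) && p_ends(word, "l")) {
    word <- substr(word, 1, nchar(word) - 1)
  }
  word
}

#' @rdname stemmers
#' @export
porter_stem <- function(words) {
  vapply(mg_normalize(words), porter_stem_one, character(1), USE.NAMES = FALSE)
}

# ---- Spanish: Snowball-style --------------------------------------------

es_vowels <- c("a", "e", "i", "o", "u", "á", "é", "í",
               "ó", "ú", "ü")

es_is_vowel <- function(ch) ch %in% es_vowels

# region start positions (1-based index of first character of region;
# n+1 when the region is empty)
es_regions <- function(word) {
  ch <- strsplit(word, "", fixed = TRUE)[[1]]
  n <- length(ch)
  vow <- vapply(ch, es_is_vowel, logical(1), USE.NAMES = FALSE)

  region_after <- function(start) {
    # first non-vowel following a vowel, at or after `start`
    i <- start
    while (i <= n && !vow[i]) i <- i + 1L        # find a vowel
    while (i <= n && vow[i]) i <- i + 1L         # find following consonant
    min(i + 1L, n + 1L)
  }
  r1 <- region_after(1L)
  r2 <- region_after(r1)

  # RV
  rv <- n + 1L
  if (n >= 3) {
    if (!vow[2]) {               # X C ... : after next vowel following pos 2
      i <- 3L
      while (i <= n && !vow[i]) i <- i + 1L
      rv <- min(i + 1L, n + 1L)
    } else if (vow[1] && vow[2]) {  # V V ... : after next consonant
      i <- 3L
      while (i <= n && vow[i]) i <- i + 1L
      rv <- min(i + 1L, n + 1L)
    } else {                     # C V ... : after third letter
      rv <- 4L
    }
  }
  list(r1 = r1, r2 = r2, rv = rv)
}

es_in_region <- function(word, suffix, region_start) {
  # TRUE when `suffix` lies entirely within the region starting at region_start
  (nchar(word) - nchar(suffix) + 1L) >= region_start
}

es_ends <- function(word, suffix) {
  n <- nchar(word); k <- nchar(suffix)
  n >= k && substr(word, n - k + 1, n) == suffix
}

es_longest_ending <- function(word, suffixes) {
  hits <- suffixes[vapply(suffixes, function(s) es_ends(word, s), logical(1))]
  if (length(hits) == 0) return(NULL)
  hits[which.max(nchar(hits))]
}

es_deaccent <- function(x) {
  chartr("áéíóú", "aeiou", x)
}

spanish_stem_one <- function(word) {
  if (nchar(word) <= 2) return(es_deaccent(word))
  rg <- es_regions(word)

  # step 0: attached pronouns after gerund/infinitive endings
  pronouns <- c("selas", "selos", "sela", "selo", "las", "les", "los",
                "nos", "me", "se", "la", "le", "lo")
  pr <- es_longest_ending(word, pronouns)
  if (!is.null(pr)) {
    base <- substr(word, 1, nchar(word) - nchar(pr))
    acc <- c("iéndo", "ándo", "ár", "ér", "ír")
    pln <- c("iendo", "yendo", "ando", "ar", "er", "ir")
    a <- es_longest_ending(base, acc)
    p <- es_longest_ending(base, pln)
    if (!is.null(a) && es_in_region(word, paste0(a, pr), rg$rv)) {
      # accented ending: drop pronoun, restore the unaccented ending
      word <- paste0(substr(base, 1, nchar(base) - nchar(a)), es_deaccent(a))
      rg <- es_regions(word)
    } else if (!is.null(p) && es_in_region(word, paste0(p, pr), rg$rv) &&
               (p != "yendo" ||
                es_ends(substr(base, 1, nchar(base) - 5), "u"))) {
      word <- base
      rg <- es_regions(word)
    }
  }

  orig <- word

  # step 1: standard suffixes
  del_r2 <- c("amientos", "imientos", "amiento", "imiento", "anzas", "ismos",
              "ables", "ibles", "istas", "anza", "icos", "icas", "ismo",
              "able", "ible", "ista", "osos", "osas", "ico", "ica", "oso",
              "osa")
  ador_r2 <- c("aciones", "adoras", "adores", "ancias", "ación", "adora",
               "ante", "antes", "ancia", "ador")
  s <- es_longest_ending(word, c(del_r2, ador_r2,
                                 "logías", "logía",
                                 "uciones", "ución",
                                 "encias", "encia",
                                 "amente", "mente",
                                 "idades", "idad",
                                 "ivas", "ivos", "iva", "ivo"))
  if (!is.null(s)) {
    base <- substr(word, 1, nchar(word) - nchar(s))
    if (s %in% del_r2) {
      if (es_in_region(word, s, rg$r2)) word <- base
    } else if (s %in% ador_r2) {
      if (es_in_region(word, s, rg$r2)) {
        word <- base
        if (es_ends(word, "ic") && es_in_region(word, "ic", rg$r2)) {
          word <- substr(word, 1, nchar(word) - 2)
        }
      }
    } else if (s %in% c("logías", "logía")) {
      if (es_in_region(word, s, rg$r2)) word <- paste0(base, "log")
    } else if (s %in% c("uciones", "ución")) {
      if (es_in_region(word, s, rg$r2)) word <- paste0(base, "u")
    } else if (s %in% c("encias", "encia")) {
      if (es_in_region(word, s, rg$r2)) word <- paste0(base, "ente")
    } else if (s == "amente") {
      if (es_in_region(word, s, rg$r1)) {
        word <- base
        if (es_ends(word, "iv") && es_in_region(word, "iv", rg$r2)) {
          word <- substr(word, 1, nchar(word) - 2)
          if (es_ends(word, "at") && es_in_region(word, "at", rg$r2)) {
            word <- substr(word, 1, nchar(word) - 2)
          }
        } else {
          for (suf2 in c("os", "ic", "ad")) {
            if (es_ends(word, suf2) && es_in_region(word, suf2, rg$r2)) {
              word <- substr(word, 1, nchar(word) - 2)
              break
            }
          }
        }
      }
    } else if (s == "mente") {
      if (es_in_region(word, s, rg$r2)) {
        word <- base
        for (suf2 in c("ante", "able", "ible")) {
          if (es_ends(word, suf2) && es_in_region(word, suf2, rg$r2)) {
            word <- substr(word, 1, nchar(word) - nchar(suf2))
            break
          }
        }
      }
    } else if (s %in% c("idades", "idad")) {
      if (es_in_region(word, s, rg$r2)) {
        word <- base
        for (suf2 in c("abil", "ic", "iv")) {
          if (es_ends(word, suf2) && es_in_region(word, suf2, rg$r2)) {
            word <- substr(word, 1, nchar(word) - nchar(suf2))
            break
          }
        }
      }
    } else if (s %in% c("ivas", "ivos", "iva", "ivo")) {
      if (es_in_region(word, s, rg$r2)) {
        word <- base
        if (es_ends(word, "at") && es_in_region(word, "at", rg$r2)) {
          word <- substr(word, 1, nchar(word) - 2)
        }
      }
    }
  }

  # step 2: verb suffixes, only if step 1 removed nothing
  if (word == orig) {
    y_sufs <- c("yeron", "yendo", "yamos", "yais", "yan", "yen", "yas",
                "yes", "ya", "ye", "yo", "yó")
    s <- es_longest_ending(word, y_sufs)
    done2a <- FALSE
    if (!is.null(s) && es_in_region(word, s, rg$rv) &&
        es_ends(substr(word, 1, nchar(word) - nchar(s)), "u")) {
      word <- substr(word, 1, nchar(word) - nchar(s))
      done2a <- TRUE
    }
    if (!done2a) {
      gu_sufs <- c("emos", "éis", "en", "es")
      verb_sufs <- c("aríais", "eríais", "iríais",
                     "aríamos", "eríamos", "iríamos",
                     "aremos", "eremos", "iremos", "aréis",
                     "eréis", "iréis", "arían", "erían",
                     "irían", "arías", "erías", "irías",
                     "ábamos", "iéramos", "iésemos",
                     "áramos", "ásemos", "íamos",
                     "ierais", "ieseis", "asteis", "isteis", "arais",
                     "aseis", "íais", "aría", "ería",
                     "iría", "arán", "erán", "irán",
                     "arás", "erás", "irás", "ieran",
                     "iesen", "ieron", "iendo", "ieras", "ieses", "abais",
                     "arian", "aban", "ían", "aran", "asen", "aron",
                     "ando", "aras", "ases", "ías", "ados", "idos",
                     "amos", "imos", "ará", "aré", "erá",
                     "eré", "irá", "iré", "aba", "ada",
                     "ida", "ara", "iera", "ase", "iese", "aste", "iste",
                     "ía", "ado", "ido", "an", "as", "ís",
                     "áis", "ió", "ar", "er", "ir", "ad", "ed",
                     "id", "o")
      s <- es_longest_ending(word, c(gu_sufs, verb_sufs))
      if (!is.null(s) && es_in_region(word, s, rg$rv)) {
        word <- substr(word, 1, nchar(word) - nchar(s))
        if (s %in% gu_sufs && es_ends(word, "gu")) {
          word <- substr(word, 1, nchar(word) - 1)
        }
      }
    }
  }

  # step 3: residual suffix
  rg <- es_regions(word)
  s <- es_longest_ending(word, c("os", "a", "o", "á", "í",
                                 "ó", "e", "é"))
  if (!is.null(s) && es_in_region(word, s, rg$rv)) {
    word <- substr(word, 1, nchar(word) - nchar(s))
    if (s %in% c("e", "é") && es_ends(word, "gu") &&
        es_in_region(paste0(word, s), paste0("u", s), rg$rv)) {
      word <- substr(word, 1, nchar(word) - 1)
    }
  }

  es_deaccent(word)
}

#' @rdname stemmers
#' @export
spanish_stem <- function(words) {
  vapply(mg_normalize(words), spanish_stem_one, character(1), USE.NAMES = FALSE)
}

#' Default stemmer for a language
#'
#' @param language `"en"` or `"es"`.
#' @return a function `character -> character`.
#' @export
default_stemmer <- function(language = c("en", "es")) {
  language <- match.arg(language)
  switch(language, en = porter_stem, es = spanish_stem)
}
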