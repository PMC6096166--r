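#' Parser configuration
#'
#' Tunables for the recursive morphological parser.
#'
#' @param language `"en"` or `"es"`; selects the default stemmer.
#' @param min_root_length an affix only matches if its removal leaves a
#'   root of at least this many characters (default 2).  This prevents a
#'   short term from being consumed entirely by its own affixes.
#' @param max_depth recursion guard; exceeding it signals a pathological
#'   dictionary.  Each level strips at least one character, so any depth
#'   at or above the longest expected term is safe.
#' @param variants logical flags `restore` and `drop` toggling the two
#'   non-trivial single-character root variants tried during lookup (see
#'   [root_variants()]).
#' @param stemmer stemming function used for stemmed lookups; `NULL`
#'   selects [default_stemmer()] for `language`.
#' @param decompose_found_roots when `TRUE`, a root found in a backend
#'   is still decomposed further if it contains known affixes; by
#'   default a successful lookup ends that branch.
#' @return a list of class `parser_config`.
#' @export
parser_config <- function(language = c("en", "es"),
                          min_root_length = 2L,
                          max_depth = 25L,
                          variants = c(restore = TRUE, drop = TRUE),
                          stemmer = NULL,
                          decompose_found_roots = FALSE) {
  language <- match.arg(language)
  mg_assert(min_root_length >= 1, "`min_root_length` must be >= 1")
  mg_assert(max_depth >= 1, "`max_depth` must be >= 1")
  if (is.null(stemmer)) stemmer <- default_stemmer(language)
  mg_assert(is.function(stemmer), "`stemmer` must be a function")
  structure(list(language = language,
                 min_root_length = as.integer(min_root_length),
                 max_depth = as.integer(max_depth),
                 variants = c(restore = isTRUE(variants[["restore"]]),
                              drop = isTRUE(variants[["drop"]])),
                 stemmer = stemmer,
                 decompose_found_roots = isTRUE(decompose_found_roots)),
            class = "parser_config")
}

#' Read a parser configuration from a YAML/JSON file
#'
#' Recognized keys: `language`, `min_root_length`, `max_depth`,
#' `variants` (`restore`/`drop`), `stemmer` (`"porter"`, `"spanish"` or
#' `"identity"`), `cascade` (backend name order, returned as attribute
#' `"cascade"`).
#'
#' @param path path to a YAML (or JSON, a YAML subset) file.
#' @return a [parser_config()]; cascade order, if given, as attribute.
#' @export
read_parser_config <- function(path) {
  mg_assert(file.exists(path), "config file not found: ", path)
  raw <- yaml::read_yaml(path)
  stemmer <- NULL
  if (!is.null(raw$stemmer)) {
    stemmer <- switch(raw$stemmer,
                      porter = porter_stem,
                      spanish = spanish_stem,
                      identity = function(x) mg_normalize(x),
                      mg_stop("unknown stemmer name: ", raw$stemmer))
  }
  cfg <- parser_config(
    language = raw$language %||% "en",
    min_root_length = raw$min_root_length %||% 2L,
    max_depth = raw$max_depth %||% 25L,
    variants = c(restore = raw$variants$restore %||% TRUE,
                 drop = raw$variants$drop %||% TRUE),
    stemmer = stemmer,
    decompose_found_roots = raw$decompose_found_roots %||% FALSE)
  attr(cfg, "cascade") <- raw$cascade
  cfg
}

#' Longest affix anchoring at a term edge
#'
#' Tries the dictionary's affixes of one position class longest-first
#' and returns the first whose characters anchor at the appropriate edge
#' (start for prefixes, end for suffixes) \emph{and} whose removal
#' leaves a root of at least `min_root_length` characters.
#'
#' @param term normalized term.
#' @param dict an [affix_dictionary()].
#' @param position `"prefix"` or `"suffix"`.
#' @param min_root_length minimum residual root length.
#' @return a one-row data frame (the affix entry), or `NULL` when
#'   nothing matches.
#' @export
match_edge_affix <- function(term, dict, position = c("prefix", "suffix"),
                             min_root_length = 2L) {
  position <- match.arg(position)
  cands <- candidate_affixes(dict, position)
  if (nrow(cands) == 0) return(NULL)
  n <- nchar(term)
  keep <- (n - nchar(cands$form)) >= min_root_length
  cands <- cands[keep, , drop = FALSE]
  hit <- if (position == "prefix") {
    startsWith(term, cands$form)
  } else {
    endsWith(term, cands$form)
  }
  if (!any(hit)) return(NULL)
  cands[which(hit)[1], , drop = FALSE]
}

#' Single-character root variants
#'
#' Stripping an affix can clip a character off the true root (or leave
#' one behind), so lookup tries small variants of the remainder at the
#' edge where the affix was matched.  Three candidates are generated, in
#' order: the bare remainder; the remainder with the adjacent boundary
#' character of the matched affix restored; and the remainder with one
#' character dropped at that edge.  Variants that would be empty are
#' omitted, as are duplicates.
#'
#' @param root the remainder after affix stripping (non-empty).
#' @param matched_edge `"start"` (a prefix was stripped) or `"end"`.
#' @param boundary_char the affix character adjacent to the root: the
#'   last character of a stripped prefix, or the first of a stripped
#'   suffix.
#' @param rules logical flags `restore` and `drop` enabling the two
#'   non-trivial variants.
#' @return character vector of candidate roots, bare remainder first.
#' @export
root_variants <- function(root, matched_edge = c("start", "end"),
                          boundary_char = "",
                          rules = c(restore = TRUE, drop = TRUE)) {
  matched_edge <- match.arg(matched_edge)
  mg_assert(nzchar(root), "`root` must be non-empty")
  out <- root
  if (isTRUE(rules[["restore"]]) && nzchar(boundary_char)) {
    out <- c(out, if (matched_edge == "start") paste0(boundary_char, root)
                  else paste0(root, boundary_char))
  }
  if (isTRUE(rules[["drop"]]) && nchar(root) > 1) {
    out <- c(out, if (matched_edge == "start") substr(root, 2, nchar(root))
                  else substr(root, 1, nchar(root) - 1))
  }
  unique(out)
}

#' Search a root through the backend cascade
#'
#' For each candidate from [root_variants()] (over every stripped edge),
#' each backend in cascade order is queried on the exact variant and
#' then -- for backends built with a stemmer -- on its stemmed form.
#' The first entry found wins.
#'
#' @param root remainder after affix stripping.
#' @param backends list of backends, cascade order.
#' @param edges list of `list(edge =, boundary =)` records, one per
#'   affix stripped at this level (empty list: only the bare root is
#'   tried).
#' @param config a [parser_config()].
#' @return a one-row entry data frame (with attribute `"variant"`), or
#'   `NULL` if every lookup fails.
#' @export
lookup_root <- function(root, backends, edges = list(),
                        config = parser_config()) {
  if (!nzchar(root) || length(backends) == 0) return(NULL)
  variants <- root
  for (e in edges) {
    variants <- c(variants,
                  root_variants(root, e$edge, e$boundary, config$variants))
  }
  variants <- unique(variants)
  for (v in variants) {
    for (b in backends) {
      bname <- if (!is.null(b$name)) b$name else "backend"
      res <- tryCatch(lookup(b, v),
                      error = function(e) {
                        mg_stop("backend '", bname, "' failed on '", v,
                                "': ", conditionMessage(e))
                      })
      if (nrow(res) == 0 && inherits(b, "lexicon_backend") &&
          !is.null(b$stems)) {
        res <- lookup(b, v, stemmed = TRUE)
      }
      if (nrow(res) > 0) {
        entry <- res[1, , drop = FALSE]
        attr(entry, "variant") <- v
        return(entry)
      }
    }
  }
  NULL
}

mp_unit <- function(surface, kind, definition, source) {
  data.frame(surface = surface, kind = kind, definition = definition,
             source = source, stringsAsFactors = FALSE)
}

#' Parse a term into glossed morphological units
#'
#' The recursive decomposition at the heart of the package.  The term is
#' normalized, split on hyphens and any other non-letter characters, and
#' each letter fragment is parsed:
#'
#' 1. the longest matching prefix is stripped, then the longest matching
#'    suffix, and their dictionary definitions attached;
#' 2. the remainder is searched through the backend cascade
#'    ([lookup_root()]); a hit makes it a glossed \emph{root} unit;
#' 3. otherwise, if an affix was stripped this level, the remainder is
#'    re-entered into the same process;
#' 4. a remainder with no affix match and no lookup hit becomes a
#'    \emph{residue} unit, glossed by itself.
#'
#' Working from longest to shortest affixes avoids spurious matches
#' (\emph{anti-} in \emph{antihero} rather than \emph{a-}).
#'
#' @param term the input term (assumed difficult; any case).
#' @param dict an [affix_dictionary()] for the term's language.
#' @param backends list of lexicon backends, cascade order (may be
#'   empty).
#' @param config a [parser_config()].
#' @return an object of class `morph_parse`: list with `term` (the
#'   normalized input), `units` (data frame `surface`, `kind`,
#'   `definition`, `source`, in left-to-right term order) and `depth`
#'   (recursion levels consumed).  Unit surfaces concatenate to the
#'   normalized term exactly.
#' @examples
#' d <- affix_dictionary(
#'   data.frame(form = c("anti-", "a-"), position = "prefix",
#'              definition = c("against", "not, without")),
#'   language = "en")
#' parse_term("antihero", d)$units
#' @export
parse_term <- function(term, dict, backends = list(),
                       config = parser_config()) {
  mg_assert(inherits(dict, "affix_dictionary"), "`dict` is not an affix_dictionary")
  mg_assert(length(term) == 1 && is.character(term), "`term` must be one string")
  norm <- mg_normalize(term)
  mg_assert(nzchar(norm), "term is empty after normalization")

  runs <- stringi::stri_extract_all_regex(norm, "\\p{L}+|\\P{L}+")[[1]]
  units <- list()
  depth_used <- 0L
  for (run in runs) {
    if (!has_only_letters(run)) {
      # separators are preserved for reconstruction but carry no gloss
      units[[length(units) + 1L]] <-
        mp_unit(run, "separator", "", "separator")
      next
    }
    res <- parse_fragment(run, dict, backends, config, depth = 1L)
    units[[length(units) + 1L]] <- res$units
    depth_used <- max(depth_used, res$depth)
  }
  units <- do.call(rbind, units)
  rownames(units) <- NULL
  out <- structure(list(term = norm, units = units, depth = depth_used),
                   class = "morph_parse")
  mg_assert(paste(units$surface, collapse = "") == norm,
            "internal error: parse does not reconstruct the term")
  out
}

parse_fragment <- function(frag, dict, backends, config, depth) {
  if (depth > config$max_depth) {
    mg_stop("recursion depth exceeded max_depth = ", config$max_depth,
            " while parsing '", frag, "' (dictionary pathology?)")
  }
  pre <- match_edge_affix(frag, dict, "prefix", config$min_root_length)
  rem <- if (is.null(pre)) frag else
    substr(frag, nchar(pre$form) + 1L, nchar(frag))
  suf <- match_edge_affix(rem, dict, "suffix", config$min_root_length)
  if (!is.null(suf)) rem <- substr(rem, 1L, nchar(rem) - nchar(suf$form))

  edges <- list()
  if (!is.null(pre)) {
    edges <- c(edges, list(list(
      edge = "start",
      boundary = substr(pre$form, nchar(pre$form), nchar(pre$form)))))
  }
  if (!is.null(suf)) {
    edges <- c(edges, list(list(edge = "end",
                                boundary = substr(suf$form, 1L, 1L))))
  }
  stripped <- !is.null(pre) || !is.null(suf)
  hit <- lookup_root(rem, backends, edges, config)

  mid <- NULL
  depth_used <- depth
  if (!is.null(hit) && !config$decompose_found_roots) {
    mid <- mp_unit(rem, "root", hit$text, hit$source)
  } else if (stripped) {
    inner <- parse_fragment(rem, dict, backends, config, depth + 1L)
    depth_used <- inner$depth
    if (!is.null(hit) && nrow(inner$units) == 1 &&
        inner$units$kind == "residue") {
      # deeper decomposition found nothing; fall back to the lookup hit
      mid <- mp_unit(rem, "root", hit$text, hit$source)
      depth_used <- depth
    } else {
      mid <- inner$units
    }
  } else if (!is.null(hit)) {
    mid <- mp_unit(rem, "root", hit$text, hit$source)
  } else {
    mid <- mp_unit(rem, "residue", rem, "unresolved")
  }

  units <- mid
  if (!is.null(pre)) {
    units <- rbind(mp_unit(pre$form, "prefix", pre$definition,
                           "affix_dictionary"), units)
  }
  if (!is.null(suf)) {
    units <- rbind(units, mp_unit(suf$form, "suffix", suf$definition,
                                  "affix_dictionary"))
  }
  list(units = units, depth = depth_used)
}

#' @export
print.morph_parse <- function(x, ...) {
  cat(sprintf("<morph_parse '%s' (%d units, depth %d)>\n",
              x$term, nrow(x$units), x$depth))
  print(x$units)
  invisible(x)
}
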