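#' Assemble an aligned explanation from a parse
#'
#' Converts a [parse_term()] result into an explanation record: one
#' `(surface, definition)` segment per morphological unit, in term
#' order.  Residue units (and separators) are glossed by their own
#' surface -- the reader at least sees which part of the word could not
#' be explained.
#'
#' @param parse a `morph_parse`.
#' @param source name recorded as the explanation's source.
#' @return an object of class `explanation` with fields `term`,
#'   `source`, `style` (`"affix_gloss"`) and `segments`.
#' @export
build_explanation <- function(parse, source = "morphgloss") {
  mg_assert(inherits(parse, "morph_parse"), "`parse` is not a morph_parse")
  mg_assert(nrow(parse$units) > 0, "cannot build an explanation from an empty parse")
  u <- parse$units
  definition <- ifelse(u$kind == "separator", u$surface, u$definition)
  structure(list(term = parse$term, source = source, style = "affix_gloss",
                 segments = data.frame(surface = u$surface,
                                       definition = definition,
                                       stringsAsFactors = FALSE)),
            class = "explanation")
}

#' Single-text explanation from a backend entry
#'
#' @param term the explained term.
#' @param text explanation text.
#' @param style `"synonym"`, `"summary"` or `"affix_gloss"`.
#' @param source source name.
#' @return an `explanation` object.
#' @export
explanation <- function(term, text, style, source) {
  mg_assert(style %in% c("synonym", "summary", "affix_gloss"),
            "unknown explanation style: ", style)
  structure(list(term = term, source = source, style = style, text = text),
            class = "explanation")
}

# quote a rendered field when it contains the separator or a quote
gloss_quote <- function(x) {
  need <- grepl('[-"]', x)
  x[need] <- paste0('"', gsub('"', '""', x[need]), '"')
  x
}

# inverse of gloss_quote on one rendered line
split_gloss_line <- function(line) {
  out <- character()
  buf <- ""
  in_q <- FALSE
  chars <- strsplit(line, "", fixed = TRUE)[[1]]
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (in_q) {
      if (ch == '"') {
        if (i < length(chars) && chars[i + 1L] == '"') {
          buf <- paste0(buf, '"'); i <- i + 1L
        } else in_q <- FALSE
      } else buf <- paste0(buf, ch)
    } else if (ch == '"') {
      in_q <- TRUE
    } else if (ch == "-") {
      out <- c(out, buf); buf <- ""
    } else buf <- paste0(buf, ch)
    i <- i + 1L
  }
  c(out, buf)
}

mg_palette <- c("red", "green", "yellow", "blue", "magenta", "cyan",
                "bright_red", "bright_green")
mg_ansi_codes <- c(red = 31, green = 32, yellow = 33, blue = 34,
                   magenta = 35, cyan = 36, bright_red = 91,
                   bright_green = 92)
mg_html_colors <- c(red = "#cc0000", green = "#007700", yellow = "#b58900",
                    blue = "#0044cc", magenta = "#aa00aa", cyan = "#008888",
                    bright_red = "#ff5555", bright_green = "#55cc55")

#' Render an explanation
#'
#' Aligned-gloss explanations render as two lines: the hyphen-joined
#' unit surfaces above the hyphen-joined definitions, so the i-th piece
#' of the word sits over its own gloss.  In `ansi` and `html` modes the
#' i-th surface and i-th definition additionally share a colour from a
#' fixed 8-colour cycle, relating unit to gloss at sight.  Fields
#' containing the separator are quoted so plain rendering stays
#' reversible.  Synonym/summary explanations render as `term: text`.
#'
#' @param expl an `explanation`.
#' @param mode `"plain"`, `"ansi"` or `"html"`.
#' @return a single string (two `\n`-separated lines for aligned
#'   glosses).
#' @export
render <- function(expl, mode = c("plain", "ansi", "html")) {
  mg_assert(inherits(expl, "explanation"), "`expl` is not an explanation")
  mode <- match.arg(mode)
  if (expl$style != "affix_gloss") {
    return(paste0(expl$term, ": ", expl$text))
  }
  seg <- expl$segments
  n <- nrow(seg)
  cols <- mg_palette[((seq_len(n) - 1L) %% length(mg_palette)) + 1L]
  wrap <- switch(mode,
    plain = function(x, col) x,
    ansi = function(x, col) sprintf("\033[%dm%s\033[0m", mg_ansi_codes[[col]], x),
    html = function(x, col) sprintf('<span style="color:%s">%s</span>',
                                    mg_html_colors[[col]], x))
  top <- mapply(wrap, gloss_quote(seg$surface), cols, USE.NAMES = FALSE)
  bot <- mapply(wrap, gloss_quote(seg$definition), cols, USE.NAMES = FALSE)
  paste(paste(top, collapse = "-"), paste(bot, collapse = "-"), sep = "\n")
}

#' @export
print.explanation <- function(x, ...) {
  cat(sprintf("<%s explanation for '%s' from %s>\n", x$style, x$term, x$source))
  cat(render(x, "plain"), "\n")
  invisible(x)
}

# evaluate expr under a temporary RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' A parser wrapped as an explanation source
#'
#' Lets the morphological parser sit alongside lexicon and embedding
#' backends in [explain_with_all_sources()].  The parser is considered
#' to cover a term when the parse resolves at least one unit (affix or
#' root); a parse that is pure residue explains nothing.
#'
#' @param dict an [affix_dictionary()].
#' @param backends backend cascade consulted for roots.
#' @param config a [parser_config()].
#' @param name source name.
#' @return an object of class `parser_source`.
#' @export
parser_source <- function(dict, backends = list(), config = parser_config(),
                          name = "morphgloss") {
  structure(list(dict = dict, backends = backends, config = config,
                 name = name),
            class = "parser_source")
}

#' Explanations for a term from every configured source
#'
#' Queries each source once; sources that do not cover the term are
#' absent from the result.  For multi-sense lexicons the primary sense
#' is used.  The presentation order is randomized under `seed`, mirroring
#' how candidate explanations are shuffled before expert rating.
#'
#' @param term the term to explain.
#' @param sources named list of sources ([lexicon_backend()],
#'   [embedding_table()] or [parser_source()] objects).
#' @param seed integer seed controlling presentation order.
#' @return list of `explanation` objects (possibly empty).
#' @export
explain_with_all_sources <- function(term, sources, seed = 1L) {
  mg_assert(length(sources) > 0, "no sources configured")
  mg_assert(!is.null(names(sources)) && all(nzchar(names(sources))),
            "`sources` must be a named list")
  out <- list()
  for (nm in names(sources)) {
    src <- sources[[nm]]
    if (inherits(src, "parser_source")) {
      p <- parse_term(term, src$dict, src$backends, src$config)
      if (any(p$units$kind %in% c("prefix", "suffix", "root"))) {
        e <- build_explanation(p, source = nm)
        out[[length(out) + 1L]] <- e
      }
    } else {
      hits <- lookup(src, term)
      if (nrow(hits) > 0) {
        out[[length(out) + 1L]] <-
          explanation(mg_normalize(term), hits$text[1], hits$style[1], nm)
      }
    }
  }
  if (length(out) > 1) {
    out <- with_seed(seed, sample(out))
  }
  out
}
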