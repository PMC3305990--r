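# Plain-text network exchange format and DOT graph export.
#
# Document layout:
#   # comment
#   species X1 X2 X3
#   2 X1 -> X2 ; k=1e7
#   X5 -> 0 ; k=0.1
# One reaction per line; complexes in the formula syntax of
# parse_complex(); "0" is the zero complex.  Rates are written with 12
# significant digits so a write/parse round trip is value-stable.

#' Read a reaction network from the plain-text exchange format
#'
#' @param text character vector of document lines, or a single string with
#'   embedded newlines. Give either `text` or `file`.
#' @param file path to a document file.
#' @return a `crn` object.
#' @details Each malformed construct is reported with its line number:
#'   unknown species, malformed stoichiometry, self-loop reactions,
#'   nonpositive rates and duplicate reactions (for the same ordered
#'   complex pair) are all distinct errors rather than silently merged.
#' @export
#' @examples
#' net <- read_crn(text = c("species X1 X2", "2 X1 -> X2 ; k=1.5"))
#' reactions(net)
read_crn <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file)) stop("give exactly one of text, file")
  if (!is.null(file)) text <- readLines(file)
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  species <- NULL
  src <- character(0); tgt <- character(0); rate <- numeric(0)
  lineno <- integer(0)
  extra <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(sub("#.*$", "", lines[i]))
    if (ln == "") next
    if (grepl("^species\\b", ln)) {
      species <- strsplit(trimws(sub("^species", "", ln)), "\\s+")[[1]]
      next
    }
    if (grepl("^complex\\b", ln)) {
      extra <- c(extra, list(c(trimws(sub("^complex", "", ln)), i)))
      next
    }
    mm <- regmatches(ln, regexec(
      "^(.*?)->(.*?);\\s*k\\s*=\\s*([-+0-9.eE]+)\\s*$", ln))[[1]]
    if (length(mm) == 0) {
      stop("line ", i, ": malformed reaction line: '", lines[i], "'")
    }
    k <- suppressWarnings(as.numeric(mm[4]))
    if (!is.finite(k)) stop("line ", i, ": unreadable rate: '", mm[4], "'")
    if (k <= 0) stop("line ", i, ": nonpositive rate: ", k)
    src <- c(src, trimws(mm[2])); tgt <- c(tgt, trimws(mm[3]))
    rate <- c(rate, k); lineno <- c(lineno, i)
  }
  if (length(src) == 0) stop("document contains no reactions")
  if (is.null(species)) {
    stop("document must declare species before the reactions")
  }
  canon <- function(f, i) {
    tryCatch(format_complex(parse_complex(f, species)),
             error = function(e) stop("line ", i, ": ", conditionMessage(e),
                                      call. = FALSE))
  }
  csrc <- mapply(canon, src, lineno)
  ctgt <- mapply(canon, tgt, lineno)
  if (any(csrc == ctgt)) {
    i <- which(csrc == ctgt)[1]
    stop("line ", lineno[i], ": self-loop reaction: '", src[i], " -> ",
         tgt[i], "'")
  }
  dup <- duplicated(paste(csrc, "->", ctgt))
  if (any(dup)) {
    i <- which(dup)[1]
    stop("line ", lineno[i], ": duplicate reaction: '", csrc[i], " -> ",
         ctgt[i], "'")
  }
  net <- crn(data.frame(source = src, target = tgt, rate = rate),
             species = species)
  for (ex in extra) {
    lab <- tryCatch(format_complex(parse_complex(ex[1], species)),
                    error = function(e) stop("line ", ex[2], ": ",
                                             conditionMessage(e),
                                             call. = FALSE))
    if (!(lab %in% net$complexes)) net <- add_complex(net, lab)
  }
  net
}

#' Write a reaction network in the plain-text exchange format
#'
#' Output is deterministic: species in declaration order, reactions ordered
#' by source then target complex index. Rates keep 12 significant digits,
#' making `read_crn(text = write_crn(net))` reproduce `net` to that
#' precision.
#'
#' @param net a `crn` object.
#' @param file optional path; when given the document is written there.
#' @return the document as a character vector of lines (invisibly when
#'   `file` is given).
#' @export
write_crn <- function(net, file = NULL) {
  stopifnot(inherits(net, "crn"))
  rx <- reactions(net)
  isolated <- setdiff(net$complexes, c(rx$source, rx$target))
  lines <- c(paste("species", paste(net$species, collapse = " ")),
             if (length(isolated)) paste("complex", isolated),
             sprintf("%s -> %s ; k=%.12g", rx$source, rx$target, rx$rate))
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Export a reaction graph in DOT format
#'
#' One node per complex (labelled with its formula), one directed edge per
#' reaction (labelled with its rate). When a [core_reactions()] report is
#' supplied, core reactions are drawn solid and non-core reactions dashed,
#' the usual convention for dense-realization figures.
#'
#' @param net a `crn` object.
#' @param core optional `core_report` for `net`.
#' @param name graph name.
#' @return DOT source as a single string.
#' @export
#' @examples
#' cat(crn_to_dot(example_positive_feedback()))
crn_to_dot <- function(net, core = NULL, name = "crn") {
  stopifnot(inherits(net, "crn"))
  rx <- reactions(net)
  ids <- stats::setNames(sprintf("c%d", seq_along(net$complexes)),
                         net$complexes)
  nodes <- sprintf("  %s [label=\"%s\"];", ids, net$complexes)
  dashed <- rep(FALSE, nrow(rx))
  if (!is.null(core)) {
    stopifnot(inherits(core, "core_report"))
    nc <- paste(core$non_core$source, "->", core$non_core$target)
    dashed <- paste(rx$source, "->", rx$target) %in% nc
  }
  edges <- sprintf("  %s -> %s [label=\"%.6g\"%s];",
                   ids[rx$source], ids[rx$target], rx$rate,
                   ifelse(dashed, ", style=dashed", ""))
  paste(c(sprintf("digraph %s {", name), nodes, edges, "}", ""),
        collapse = "\n")
}
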