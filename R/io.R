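## Forest and graph file formats.
##
## Forests: Newick, one tree per line. Leaves carry NHX tags
##   name[&&NHX:S=species:P=1]   (P = 1 Present, 0 Absent)
## roots may carry G=<homology group> (default: the root label). Branch
## lengths, when present on every edge, populate node times tc/td by
## root-to-node accumulation. Single-leaf trees ("a[&&NHX:P=1];") are valid:
## unduplicated homology groups are the common case.
##
## Graphs: TSV edge lists with header "#directed=0|1 selfloops=0|1".

#' Read a duplication forest from a Newick file
#'
#' @param path file path, or use \code{text=} for literal input.
#' @param text optional character scalar/vector of Newick lines (overrides
#'   \code{path}).
#' @return a [duplication_forest()].
#' @export
read_forest <- function(path, text = NULL) {
  lines <- if (is.null(text)) readLines(path, warn = FALSE) else
    unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("no trees found")
  parsed <- lapply(lines, parse_newick_tree)

  label <- character(0); parent <- integer(0); present <- logical(0)
  species <- character(0); group <- character(0); blen <- numeric(0)
  any_blen <- FALSE
  for (ti in seq_along(parsed)) {
    tr <- parsed[[ti]]
    off <- length(label)
    auto <- startsWith(tr$label, ".in")       # uniquify autogenerated ids
    tr$label[auto] <- paste0(".t", ti, tr$label[auto])
    label <- c(label, tr$label)
    parent <- c(parent, ifelse(is.na(tr$parent), NA_integer_, tr$parent + off))
    present <- c(present, tr$present)
    species <- c(species, tr$species)
    g <- tr$group[1]            # root is row 1 in parser output
    if (is.na(g)) g <- tr$label[1]
    group <- c(group, rep(g, length(tr$label)))
    blen <- c(blen, tr$blen)
    if (any(!is.na(tr$blen))) any_blen <- TRUE
  }
  duplication_forest(label, parent, present, species, group,
                     blen = if (any_blen) blen else NULL)
}

## Recursive-descent Newick+NHX parser for one tree. Returns parallel vectors
## in preorder (root first). Written in-package: standard tree readers drop
## the NHX payload and reject single-leaf trees.
parse_newick_tree <- function(line) {
  line <- sub(";\\s*$", "", trimws(line))
  env <- new.env(parent = emptyenv())
  env$s <- strsplit(line, "")[[1]]
  env$i <- 1L
  env$label <- character(0); env$parent <- integer(0); env$present <- logical(0)
  env$species <- character(0); env$group <- character(0); env$blen <- numeric(0)
  env$autoid <- 0L

  peek <- function() if (env$i <= length(env$s)) env$s[env$i] else ""
  advance <- function() env$i <- env$i + 1L

  read_token <- function() {
    out <- character(0)
    while (env$i <= length(env$s) && !(peek() %in% c("(", ")", ",", ":", "[")))
      { out <- c(out, peek()); advance() }
    paste(out, collapse = "")
  }
  read_nhx <- function() {
    if (peek() != "[") return(NULL)
    j <- env$i
    depth <- 0L
    repeat {
      if (j > length(env$s)) stop("unterminated [ comment in Newick input")
      if (env$s[j] == "[") depth <- depth + 1L
      if (env$s[j] == "]") { depth <- depth - 1L; if (depth == 0L) break }
      j <- j + 1L
    }
    com <- paste(env$s[(env$i + 1L):(j - 1L)], collapse = "")
    env$i <- j + 1L
    if (!startsWith(com, "&&NHX")) return(list())
    parts <- strsplit(sub("^&&NHX:?", "", com), ":", fixed = TRUE)[[1]]
    parts <- parts[nzchar(parts)]
    kv <- strsplit(parts, "=", fixed = TRUE)
    bad <- vapply(kv, length, 1L) != 2L
    if (any(bad)) stop("malformed NHX tag: [", com, "]")
    stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  }

  emit <- function(parent) {
    k <- length(env$label) + 1L
    env$label[k] <- NA_character_; env$parent[k] <- parent
    env$present[k] <- NA; env$species[k] <- NA_character_
    env$group[k] <- NA_character_; env$blen[k] <- NA_real_
    k
  }

  node <- function(parent) {
    k <- emit(parent)
    nchild <- 0L
    if (peek() == "(") {
      advance()
      node(k); nchild <- 1L
      while (peek() == ",") { advance(); node(k); nchild <- nchild + 1L }
      if (peek() != ")") stop("expected ')' at position ", env$i)
      advance()
      if (nchild > 2L)
        stop("non-binary tree: node with ", nchild, " children at position ", env$i)
    }
    lab <- read_token()
    tags <- read_nhx()
    if (peek() == ":") {
      advance()
      env$blen[k] <- as.numeric(read_token())
      t2 <- read_nhx()
      if (!is.null(t2)) tags <- c(tags, t2)
    }
    if (!nzchar(lab)) { env$autoid <- env$autoid + 1L
                        lab <- paste0(".in", env$autoid) }
    env$label[k] <- lab
    if (!is.null(tags) && length(tags)) {
      if ("S" %in% names(tags)) env$species[k] <- tags[["S"]]
      if ("G" %in% names(tags)) env$group[k] <- tags[["G"]]
      if ("P" %in% names(tags)) {
        p <- tags[["P"]]
        if (!p %in% c("0", "1")) stop("malformed NHX tag: P=", p)
        env$present[k] <- p == "1"
      }
    }
    if (nchild == 0L && is.na(env$present[k])) env$present[k] <- TRUE
    k
  }

  node(NA_integer_)
  if (env$i <= length(env$s)) stop("trailing characters in Newick input")
  out <- as.list(env)[c("label", "parent", "present", "species", "group", "blen")]

  ## collapse unary wrapper nodes, e.g. "((a,b)r);": splice the single child
  ## into its grandparent (summing branch lengths). Deeper unary chains are a
  ## format error only if they leave a node with one sibling-less child that
  ## is itself structural; here any unary node is collapsed.
  repeat {
    nkids <- tabulate(out$parent[!is.na(out$parent)], nbins = length(out$label))
    isleaf <- nkids == 0L
    unary <- which(nkids == 1L)
    if (!length(unary)) break
    u <- unary[1]
    ch <- which(!is.na(out$parent) & out$parent == u)
    out$parent[ch] <- out$parent[u]
    if (!is.na(out$blen[u]))
      out$blen[ch] <- ifelse(is.na(out$blen[ch]), 0, out$blen[ch]) + out$blen[u]
    if (is.na(out$group[ch]) && !is.na(out$group[u])) out$group[ch] <- out$group[u]
    keep <- setdiff(seq_along(out$label), u)
    remap <- match(seq_along(out$label), keep)
    out$parent <- remap[out$parent][keep]
    for (nm in c("label", "present", "species", "group", "blen"))
      out[[nm]] <- out[[nm]][keep]
  }
  ## root must be row 1 for group attribution downstream
  if (length(out$label) && is.na(out$parent[1]) == FALSE) {
    r <- which(is.na(out$parent))[1]
    ord <- c(r, setdiff(seq_along(out$label), r))
    remap <- match(seq_along(out$label), ord)
    out$parent <- remap[out$parent][ord]
    for (nm in c("label", "present", "species", "group", "blen"))
      out[[nm]] <- out[[nm]][ord]
  }
  out
}

#' Write a duplication forest as Newick/NHX
#'
#' One tree per line; inverse of [read_forest()] (round-trip identity on
#' labels, Present/Absent flags, species, groups, and branch lengths).
#'
#' @param forest a [duplication_forest()].
#' @param path output file; omit (NULL) to return the lines invisibly.
#' @return character vector of Newick lines, invisibly.
#' @export
write_forest <- function(forest, path = NULL) {
  has_len <- !all(is.na(forest$tc))
  fmt <- function(u, is_root) {
    leaf <- is.na(forest$left[u])
    core <- if (leaf) forest$label[u] else
      paste0("(", fmt(forest$left[u], FALSE), ",", fmt(forest$right[u], FALSE), ")",
             forest$label[u])
    tags <- character(0)
    if (!is.na(forest$species[u])) tags <- c(tags, paste0("S=", forest$species[u]))
    if (leaf) tags <- c(tags, paste0("P=", as.integer(forest$present[u])))
    if (is_root && !identical(forest$group[u], forest$label[u]))
      tags <- c(tags, paste0("G=", forest$group[u]))
    if (length(tags)) core <- paste0(core, "[&&NHX:", paste(tags, collapse = ":"), "]")
    if (has_len && !is_root)
      core <- paste0(core, ":", format(forest$tc[u] - forest$tc[forest$parent[u]],
                                       digits = 12))
    core
  }
  lines <- vapply(forest$roots, function(r) paste0(fmt(r, TRUE), ";"), "")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Read an interaction graph from a TSV edge list
#'
#' First line is a header of the form \code{#directed=0|1 selfloops=0|1};
#' remaining lines are two tab-separated node ids. Isolated nodes may be
#' declared as lines with a single id.
#'
#' @param path file path, or \code{text=} literal lines.
#' @param text optional character input overriding \code{path}.
#' @return an [interaction_graph()].
#' @export
read_graph <- function(path, text = NULL) {
  lines <- if (is.null(text)) readLines(path, warn = FALSE) else
    unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines) || !startsWith(lines[1], "#"))
    stop("missing '#directed=.. selfloops=..' header")
  hd <- lines[1]
  getflag <- function(key) {
    m <- regmatches(hd, regexec(paste0(key, "=([01])"), hd))[[1]]
    if (length(m) < 2) stop("header must set ", key, "=0|1")
    m[2] == "1"
  }
  directed <- getflag("directed"); selfloops <- getflag("selfloops")
  body <- lines[-1]
  if (!length(body))
    return(interaction_graph(character(0), directed = directed, selfloops = selfloops))
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- vapply(fields, length, 1L)
  if (any(nf > 2L)) stop("edge lines must have at most two columns")
  singles <- unlist(fields[nf == 1L])
  ed <- fields[nf == 2L]
  em <- if (length(ed)) do.call(rbind, ed) else matrix(character(0), 0, 2)
  interaction_graph(nodes = unique(c(singles, as.vector(em))), edges = em,
                    directed = directed, selfloops = selfloops)
}

#' Write an interaction graph as a TSV edge list
#' @param graph an [interaction_graph()].
#' @param path output file; NULL returns lines invisibly.
#' @return character lines, invisibly.
#' @export
write_graph_tsv <- function(graph, path = NULL) {
  hd <- sprintf("#directed=%d selfloops=%d",
                as.integer(graph$directed), as.integer(graph$selfloops))
  used <- unique(as.vector(graph$edges))
  iso <- setdiff(graph$nodes, used)
  lines <- c(hd,
             if (nrow(graph$edges)) paste(graph$edges[, 1], graph$edges[, 2], sep = "\t"),
             iso)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
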