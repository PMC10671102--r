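#' Haplogroup assignment from a variant-annotated tree
#'
#' A haplogroup tree is a rooted hierarchy whose nodes carry
#' haplogroup-defining substitutions in rCRS-relative notation. A
#' haplotype is scored against every node as the number of defining
#' variants matched along the root-to-node path minus a penalty of 0.5 per
#' expected-but-absent variant; private variants are not penalized. Back
#' mutations are written with a trailing `!` (e.g. `263A!`) and denote the
#' stated (reference) base, so a haplotype with no variant at the position
#' matches them — this is how the reference-identical haplotype scores into
#' its own haplogroup rather than the root.
#'
#' @name haplogrouper
NULL

.parse_tree_token <- function(token) {
  m <- regmatches(toupper(token),
                  regexec("^([0-9]+)([ACGTRYSWKMBDHVN])(!?)$", toupper(token)))[[1]]
  if (length(m) == 0L) stop("unknown tree variant token: '", token, "'")
  data.frame(pos = as.integer(m[2]), base = m[3], back = m[4] == "!",
             stringsAsFactors = FALSE)
}

#' Load a haplogroup tree from an indented text file
#'
#' One node per line, depth given by leading indentation (tabs, or two
#' spaces per level), then `name<TAB>tokens` or `name: tokens` with
#' whitespace-separated defining-variant tokens (possibly none).
#'
#' @param path file path, or a character vector of lines via `text`.
#' @param text optional character vector of lines (overrides `path`).
#' @return Object of class `hgtree`: list of nodes, each with `name`,
#'   `parent`, `depth` and a `tokens` data.frame.
#' @export
load_haplogroup_tree <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  if (length(lines) == 0L) stop("empty haplogroup tree file")
  nodes <- list()
  stack <- character(0)   # ancestor names by depth
  for (line in lines) {
    indent <- sub("^([ \t]*).*$", "\\1", line)
    depth <- as.integer(sum(strsplit(indent, "")[[1]] == "\t") +
      floor(sum(strsplit(indent, "")[[1]] == " ") / 2))
    body <- trimws(line)
    parts <- strsplit(body, "[:\t]", perl = TRUE)[[1]]
    name <- trimws(parts[1])
    tok_text <- if (length(parts) > 1L) paste(parts[-1], collapse = " ") else ""
    tokens <- strsplit(trimws(tok_text), "[[:space:]]+")[[1]]
    tokens <- tokens[nzchar(tokens)]
    tok_df <- if (length(tokens)) do.call(rbind, lapply(tokens, .parse_tree_token))
              else data.frame(pos = integer(0), base = character(0),
                              back = logical(0), stringsAsFactors = FALSE)
    if (name %in% vapply(nodes, `[[`, character(1), "name")) {
      stop("duplicate haplogroup name: ", name)
    }
    if (depth > length(stack)) {
      stop("indentation jump at node '", name, "'")
    }
    parent <- if (depth == 0L) NA_character_ else stack[depth]
    if (depth > 0L && is.na(parent)) stop("orphan node: ", name)
    nodes[[length(nodes) + 1L]] <- list(name = name, parent = parent,
                                        depth = depth, tokens = tok_df)
    stack <- c(stack[seq_len(depth)], name)
  }
  roots <- sum(vapply(nodes, function(n) is.na(n$parent), logical(1)))
  if (roots != 1L) stop("tree must have exactly one root (found ", roots, ")")
  structure(nodes, class = "hgtree")
}

#' @export
print.hgtree <- function(x, ...) {
  cat(sprintf("<hgtree> %d nodes, root '%s'\n", length(x), x[[1]]$name))
  invisible(x)
}

#' Number of nodes in a haplogroup tree
#' @param tree `hgtree`.
#' @export
n_tree_nodes <- function(tree) length(tree)

# accumulated root-to-node token table per node
.node_paths <- function(tree) {
  by_name <- stats::setNames(seq_along(tree), vapply(tree, `[[`, character(1), "name"))
  paths <- vector("list", length(tree))
  for (i in seq_along(tree)) {
    node <- tree[[i]]
    base <- if (is.na(node$parent)) NULL else paths[[by_name[[node$parent]]]]
    paths[[i]] <- rbind(base, node$tokens)
  }
  paths
}

#' Assign a haplogroup to a haplotype
#'
#' The haplotype is restricted to `range` first; tree tokens outside the
#' range are likewise ignored, so range-restricted assignment can only
#' coarsen the result. The effective base at a position is the haplotype's
#' substitution symbol there, or the reference base when the haplotype has
#' no variant; a token matches when its stated base shares an IUPAC
#' expansion with the effective base (so a PHP `Y` matches a `C`-defining
#' token). Ties are broken towards the shallower node, then
#' lexicographically, and reported.
#'
#' @param h `mthaplotype`.
#' @param tree `hgtree`.
#' @param range `mtrange` (default full mitogenome).
#' @param ref `mtreference` used for effective reference states.
#' @return List: `best`, `score`, `matched`, `missing` (token data.frames),
#'   `private` (positions), `ties` (equally scored names), `scores`
#'   (per-node data.frame).
#' @export
assign_haplogroup <- function(h, tree, range = standard_range("mitogenome"),
                              ref = synthetic_reference()) {
  if (length(tree) == 0L) stop("empty haplogroup tree")
  hr <- restrict_to_range(h, range)
  subs <- hr$variants[hr$variants$kind == "sub", , drop = FALSE]
  eff <- function(pos) {
    i <- match(pos, subs$pos)
    ifelse(is.na(i), ref_base(ref, pos), subs$obs[i])
  }
  paths <- .node_paths(tree)
  names <- vapply(tree, `[[`, character(1), "name")
  depths <- vapply(tree, `[[`, integer(1), "depth")
  score <- numeric(length(tree))
  match_info <- vector("list", length(tree))
  for (i in seq_along(tree)) {
    tok <- paths[[i]]
    tok <- tok[in_mt_range(tok$pos, range), , drop = FALSE]
    if (nrow(tok) == 0L) {
      score[i] <- 0
      match_info[[i]] <- list(matched = tok, missing = tok)
      next
    }
    e <- eff(tok$pos)
    hit <- mapply(function(a, b) iupac_match(a, b, "pattern"), e, tok$base)
    score[i] <- sum(hit) - 0.5 * sum(!hit)
    match_info[[i]] <- list(matched = tok[hit, , drop = FALSE],
                            missing = tok[!hit, , drop = FALSE])
  }
  best_score <- max(score)
  tied <- which(score == best_score)
  o <- tied[order(depths[tied], names[tied])]
  best <- o[1]
  path_pos <- unique(paths[[best]]$pos)
  private <- setdiff(subs$pos, path_pos)
  list(best = names[best], score = best_score,
       matched = match_info[[best]]$matched,
       missing = match_info[[best]]$missing,
       private = private,
       ties = names[tied],
       scores = data.frame(name = names, depth = depths, score = score,
                           stringsAsFactors = FALSE))
}

#' Is node `a` an ancestor of (or equal to) node `b`?
#' @param tree `hgtree`.
#' @param a,b node names.
#' @return Logical.
#' @export
is_ancestor_or_equal <- function(tree, a, b) {
  names <- vapply(tree, `[[`, character(1), "name")
  parent_of <- stats::setNames(vapply(tree, `[[`, character(1), "parent"), names)
  cur <- b
  while (!is.na(cur)) {
    if (cur == a) return(TRUE)
    cur <- parent_of[[cur]]
  }
  FALSE
}

#' Packaged synthetic mini haplogroup tree
#'
#' Loads the 25-node fixture tree shipped with the package: a synthetic,
#' heavily pruned rCRS-relative hierarchy covering the haplogroups used in
#' the examples (H and subclades, U5/U8 branches, T, J, K, V, W). The
#' reference-identical haplotype is carried by H2a2a1 via back-mutation
#' tokens.
#'
#' @return `hgtree`.
#' @export
mini_haplogroup_tree <- function() {
  load_haplogroup_tree(system.file("extdata", "haplogroup_tree_synthetic.txt",
                                   package = "mitohap", mustWork = TRUE))
}
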