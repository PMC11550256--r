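# Network input/output.
#
# Extended Newick dialect: a reticulation ("hybrid") node is written #Hk; it
# appears once with its subtree, as (subtree)#Hk, and once or more as a bare
# reference #Hk.  Parsing is delegated to ape::read.evonet(); writing emits
# the dialect directly by a depth-first walk (first visit of a reticulation
# prints its subtree, later visits print the bare tag).
#
# Edge-list format: TSV with one "parent<TAB>child" line per edge,
# "#"-comment lines allowed, plus optional leaf-label lines
# "L<TAB>node<TAB>label".  Node identifiers are taken verbatim.

#' Read a phylogenetic network
#'
#' @param text Input as a character string (one network).
#' @param path Alternatively, a file to read.
#' @param format `"enewick"` (extended Newick with `#Hk` hybrid tags) or
#'   `"edgelist"` (TSV parent/child lines).
#' @return A [phylo_network()].  Node identifiers are assigned at parse time;
#'   leaf labels are preserved exactly.  Branch lengths, if present, are
#'   parsed and ignored.
#' @examples
#' read_network("((a,b)x,c)r;")
#' @export
read_network <- function(text = NULL, path = NULL,
                         format = c("enewick", "edgelist")) {
  format <- match.arg(format)
  if (is.null(text) == is.null(path)) {
    stop_input("read_network: give exactly one of text or path")
  }
  if (is.null(text)) text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (format == "enewick") read_enewick(text) else read_edgelist(text)
}

read_enewick <- function(text) {
  txt <- trimws(text)
  if (!nzchar(txt)) stop_input("parse error: empty input")
  if (!grepl(";\\s*$", txt)) stop_input("parse error: input does not end with ';'")

  # trivial single-node network: a bare (possibly labelled) root-leaf
  if (grepl("^[^(),;#]*;$", txt)) {
    lab <- sub(";$", "", txt)
    if (!nzchar(lab)) lab <- "t1"
    return(phylo_network(edges = NULL, nodes = lab))
  }

  has_hybrids <- grepl("#", txt, fixed = TRUE)
  ev <- tryCatch({
    if (has_hybrids) {
      suppressWarnings(ape::read.evonet(text = txt))
    } else {
      withCallingHandlers(
        ape::read.tree(text = txt),
        warning = function(w) stop_input(paste0("parse error: ", conditionMessage(w)))
      )
    }
  },
  error = function(e) {
    if (inherits(e, "cherrycount_error")) stop(e)
    stop_input(paste0("parse error: ", conditionMessage(e)))
  })
  if (is.null(ev)) stop_input("parse error: input is not a valid Newick string")
  ntip <- length(ev$tip.label)
  edges <- ev$edge
  if (!is.null(ev$reticulation)) edges <- rbind(edges, ev$reticulation)

  names_vec <- c(ev$tip.label,
                 if (is.null(ev$node.label)) rep("", ev$Nnode) else ev$node.label)
  names_vec <- sub("^#", "", names_vec)
  blank <- !nzchar(names_vec) | is.na(names_vec)
  names_vec[blank] <- paste0("i", seq_along(names_vec)[blank])
  if (anyDuplicated(names_vec)) {
    names_vec <- make.unique(names_vec, sep = "_")
  }

  if (anyDuplicated(ev$tip.label)) {
    stop_input(sprintf("parse error: duplicate leaf label: %s",
                       ev$tip.label[duplicated(ev$tip.label)][1L]))
  }

  N <- phylo_network(
    edges = cbind(names_vec[edges[, 1L]], names_vec[edges[, 2L]]),
    nodes = names_vec,
    leaf_labels = character(0)
  )
  # a node written only as (subtree)#Hk with no bare reference has a single
  # parent and a single child, i.e. is elementary
  if (any(in_degrees(N) == 1L & out_degrees(N) == 1L)) {
    stop_input("parse error: hybrid tag used only once (elementary node)")
  }
  leaves <- network_leaves(N)
  lab <- N$node_names[as.character(leaves)]
  names(lab) <- as.character(leaves)
  N$leaf_labels <- lab
  N
}

read_edgelist <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop_input("parse error: empty edge list")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  is_label <- vapply(parts, function(p) p[[1L]] == "L" && length(p) == 3L, logical(1))
  edge_parts <- parts[!is_label]
  bad <- which(vapply(edge_parts, length, integer(1)) != 2L)
  if (length(bad) > 0L) {
    stop_input(sprintf("parse error: line %d is neither 'parent<TAB>child' nor 'L<TAB>node<TAB>label'",
                       which(!is_label)[bad[1L]]))
  }
  labels <- character(0)
  if (any(is_label)) {
    labels <- vapply(parts[is_label], `[[`, character(1), 3L)
    names(labels) <- vapply(parts[is_label], `[[`, character(1), 2L)
    if (anyDuplicated(labels)) {
      stop_input(sprintf("parse error: duplicate leaf label: %s",
                         labels[duplicated(labels)][1L]))
    }
  }
  if (length(edge_parts) == 0L) {
    nodes <- names(labels)
    return(phylo_network(edges = NULL, nodes = nodes,
                         leaf_labels = if (length(labels)) labels else NULL))
  }
  edges <- do.call(rbind, edge_parts)
  phylo_network(edges = edges,
                leaf_labels = if (length(labels)) labels else NULL)
}

#' Write a phylogenetic network
#'
#' Serializes a network to extended Newick or to the TSV edge-list format.
#' Round trips are stable up to renumbering of node identifiers:
#' `read_network(write_network(N))` is isomorphic to `N` with leaf labels
#' preserved exactly (see [networks_isomorphic()]).
#'
#' @param N A [phylo_network()].
#' @param format `"enewick"` or `"edgelist"`.
#' @param path Optional file to write to; otherwise the text is returned.
#' @return The serialized text, invisibly when `path` is given.
#' @export
write_network <- function(N, format = c("enewick", "edgelist"), path = NULL) {
  format <- match.arg(format)
  out <- if (format == "enewick") write_enewick(N) else write_edgelist(N)
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

write_enewick <- function(N) {
  if (is.na(N$root)) stop_domain("write_network: network has no unique root")
  if (length(N$nodes) == 1L) {
    lab <- N$leaf_labels[as.character(N$root)]
    if (is.na(lab)) lab <- N$node_names[as.character(N$root)]
    return(paste0(lab, ";"))
  }
  rets <- sort(reticulation_nodes(N))
  tag <- setNames(seq_along(rets), as.character(rets))
  seen <- new.env(parent = emptyenv())
  safe <- function(x) if (grepl("^[A-Za-z0-9_.]+$", x)) x else ""
  ser <- function(v) {
    key <- as.character(v)
    if (!is.na(tag[key])) {
      if (!is.null(seen[[key]])) return(paste0("#H", tag[[key]]))
      seen[[key]] <- TRUE
      ch <- node_children(N, v)
      if (length(ch) == 0L) return(paste0("#H", tag[[key]]))
      inner <- paste(vapply(ch, ser, character(1)), collapse = ",")
      return(paste0("(", inner, ")#H", tag[[key]]))
    }
    ch <- node_children(N, v)
    if (length(ch) == 0L) {
      lab <- N$leaf_labels[key]
      if (is.na(lab)) lab <- N$node_names[key]
      return(lab)
    }
    inner <- paste(vapply(ch, ser, character(1)), collapse = ",")
    paste0("(", inner, ")", safe(N$node_names[key]))
  }
  paste0(ser(N$root), ";")
}

write_edgelist <- function(N) {
  nm <- function(v) N$node_names[as.character(v)]
  lines <- character(0)
  if (nrow(N$edges) > 0L) {
    lines <- paste0(nm(N$edges[, "parent"]), "\t", nm(N$edges[, "child"]))
  }
  if (length(N$leaf_labels) > 0L) {
    lines <- c(lines, paste0("L\t", nm(as.integer(names(N$leaf_labels))), "\t",
                             N$leaf_labels))
  }
  paste(lines, collapse = "\n")
}
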