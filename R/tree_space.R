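#' Exhaustively enumerate unrooted binary topologies
#'
#' Generates every unrooted binary tree shape over the given taxa by stepwise
#' addition (each new taxon attached to every edge of every partial tree),
#' which yields the complete, duplicate-free set of `(2n-5)!!` topologies.
#' Guarded to 3--10 taxa. An optional clade constraint keeps only topologies
#' containing that clade as a bipartition (e.g. an outgroup pair).
#'
#' @param taxa character vector of 3--10 unique labels.
#' @param constraint optional character vector, a proper subset of `taxa`,
#'   required to form a clade.
#' @return `multiPhylo`, named by canonical topology key ([topology_key()]).
#' @examples
#' length(enumerate_topologies(letters[1:4]))  # 3
#' @export
enumerate_topologies <- function(taxa, constraint = NULL) {
  taxa <- as.character(taxa)
  n <- length(taxa)
  if (anyDuplicated(taxa)) stop("taxa must be unique")
  if (n < 3 || n > 10) stop("enumeration supports 3 to 10 taxa")
  if (!is.null(constraint)) {
    if (!all(constraint %in% taxa) || length(constraint) >= n ||
        length(constraint) < 1) {
      stop("constraint must be a proper non-empty subset of taxa")
    }
  }
  # edge lists over integer nodes: leaves 1..n, internals n+1, n+2, ...
  trees <- list(cbind(n + 1L, 1:3))
  k <- 3L
  while (k < n) {
    k <- k + 1L
    w <- n + k - 2L
    trees <- unlist(lapply(trees, function(ed) {
      lapply(seq_len(nrow(ed)), function(i) {
        rbind(ed[-i, , drop = FALSE],
              c(ed[i, 1], w), c(w, ed[i, 2]), c(w, k))
      })
    }), recursive = FALSE)
  }
  nwk <- vapply(trees, edges_to_newick, "", labels = taxa, n = n)
  phys <- ape::read.tree(text = paste0(nwk, collapse = "\n"))
  if (n == 3) phys <- structure(list(phys), class = "multiPhylo")
  names(phys) <- vapply(phys, topology_key, "")
  if (anyDuplicated(names(phys))) stop("internal error: duplicate topologies")
  if (!is.null(constraint)) {
    keep <- vapply(phys, has_clade, TRUE, clade = constraint)
    phys <- phys[keep]
  }
  phys
}

# newick for an unrooted edge list, written from the internal node next to
# leaf 1 so the string is deterministic
edges_to_newick <- function(ed, labels, n) {
  adj <- vector("list", max(ed))
  for (i in seq_len(nrow(ed))) {
    adj[[ed[i, 1]]] <- c(adj[[ed[i, 1]]], ed[i, 2])
    adj[[ed[i, 2]]] <- c(adj[[ed[i, 2]]], ed[i, 1])
  }
  rec <- function(v, from) {
    if (v <= n) return(labels[v])
    kids <- setdiff(adj[[v]], from)
    paste0("(", paste(vapply(kids, rec, "", from = v), collapse = ","), ")")
  }
  root <- adj[[1]][1]
  paste0("(", paste(vapply(adj[[root]], rec, "", from = root), collapse = ","),
         ");")
}

# tip labels below each node (list indexed by node id), postorder accumulation
node_tipsets <- function(phy) {
  phy <- stats::reorder(phy, "postorder")
  ntip <- length(phy$tip.label)
  sets <- vector("list", max(phy$edge))
  for (i in seq_len(ntip)) sets[[i]] <- phy$tip.label[i]
  for (e in seq_len(nrow(phy$edge))) {
    par <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    sets[[par]] <- c(sets[[par]], sets[[ch]])
  }
  sets
}

# non-trivial splits of the unrooted shape, each written as the sorted label
# set on the side away from the reference (alphabetically first) leaf
unrooted_splits <- function(phy) {
  tips <- sort(phy$tip.label)
  ref <- tips[1]
  sets <- node_tipsets(phy)
  ntip <- length(phy$tip.label)
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])
  splits <- character(0)
  for (v in setdiff(unique(phy$edge[, 1]), root)) {
    s <- sets[[v]]
    if (ref %in% s) s <- setdiff(tips, s)
    if (length(s) >= 2 && length(s) <= ntip - 2) {
      splits <- c(splits, paste(sort(s), collapse = ","))
    }
  }
  sort(unique(splits))
}

#' Canonical topology key
#'
#' An order-invariant string identifying the unrooted tree shape with labels:
#' the sorted taxa plus the sorted non-trivial bipartitions (each written from
#' the side away from the alphabetically first leaf). Two trees get equal keys
#' iff they are the same unrooted topology; keys are stable across runs.
#'
#' @param phy a `phylo` (rooted or unrooted; rooting is ignored).
#' @return character scalar.
#' @export
topology_key <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  paste0(paste(sort(phy$tip.label), collapse = ","), ";",
         paste(unrooted_splits(phy), collapse = ";"))
}

#' Does a topology contain a clade as a bipartition?
#'
#' @param phy a `phylo`.
#' @param clade character vector of tip labels.
#' @return TRUE if `clade` is one side of an edge of the unrooted shape (or a
#'   trivial split: a single tip, or all but one).
#' @export
has_clade <- function(phy, clade) {
  tips <- phy$tip.label
  if (!all(clade %in% tips)) return(FALSE)
  k <- length(clade)
  if (k == 1 || k >= length(tips) - 1) return(TRUE)
  ref <- sort(tips)[1]
  side <- if (ref %in% clade) setdiff(tips, clade) else clade
  paste(sort(side), collapse = ",") %in% unrooted_splits(phy)
}

#' Root a topology on the edge separating an outgroup
#'
#' @param phy unrooted `phylo`.
#' @param outgroup character vector of outgroup tip labels; must be
#'   monophyletic (form a bipartition) in `phy`, else an error is raised.
#' @return rooted binary `phylo` with the ingroup and outgroup as the two
#'   children of the root.
#' @export
root_with_outgroup <- function(phy, outgroup) {
  stopifnot(inherits(phy, "phylo"))
  if (!all(outgroup %in% phy$tip.label)) stop("outgroup taxa not in tree")
  if (!has_clade(phy, outgroup)) {
    stop("outgroup is not monophyletic in this topology: ",
         paste(outgroup, collapse = ","))
  }
  r <- ape::root(ape::unroot(phy), outgroup = outgroup, resolve.root = TRUE)
  stats::reorder(r, "cladewise")
}

#' Write topologies as Newick, one per line
#'
#' @param topologies `multiPhylo` (or list of `phylo`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_topologies <- function(topologies, path) {
  txt <- vapply(topologies, ape::write.tree, "")
  writeLines(txt, path)
  invisible(path)
}
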