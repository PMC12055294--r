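# Assembly of the dated ultrametric mega-phylogeny:
# within-family JC69 distance matrices and neighbour-joining subtrees from
# aligned barcodes, grafting onto a dated family-level backbone, sister-family
# insertion for families missing from the backbone, bladj-style age
# calibration, and tip-height equalization.

#' Jukes-Cantor distances from an alignment
#'
#' Pairwise p-distances over the columns where both sequences carry an
#' unambiguous base (A/C/G/T; gaps and ambiguity codes are pairwise-deleted),
#' corrected with JC69: `d = -(3/4) log(1 - 4p/3)`. Saturated pairs
#' (`p >= 0.75`, where the correction diverges) are set to a finite ceiling
#' with a warning.
#'
#' @param seqs named character vector of equal-length aligned sequences.
#' @param ceiling distance assigned to saturated pairs (default 5).
#' @return symmetric distance matrix with zero diagonal.
#' @export
jc69_distances <- function(seqs, ceiling = 5) {
  if (length(seqs) < 2) stop_metadiv("need at least two sequences")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop_metadiv("sequences must carry unique names")
  }
  chars <- strsplit(toupper(seqs), "")
  lens <- lengths(chars)
  if (length(unique(lens)) != 1) stop_metadiv("sequences must have equal length (aligned)")
  M <- do.call(rbind, chars)
  ok <- M == "A" | M == "C" | M == "G" | M == "T"
  k <- length(seqs)
  D <- matrix(0, k, k, dimnames = list(names(seqs), names(seqs)))
  saturated <- FALSE
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      use <- ok[i, ] & ok[j, ]
      if (!any(use)) {
        stop_metadiv("no comparable ungapped columns between '",
                     names(seqs)[i], "' and '", names(seqs)[j], "'")
      }
      p <- mean(M[i, use] != M[j, use])
      if (p >= 0.75) {
        d <- ceiling
        saturated <- TRUE
      } else {
        d <- -0.75 * log(1 - 4 * p / 3)
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  if (saturated) {
    warning("saturated pair(s) (p >= 0.75); distance set to ceiling ", ceiling,
            call. = FALSE)
  }
  D
}

#' Neighbour-joining subtree from a distance matrix
#'
#' Saitou-Nei neighbour joining (via [ape::nj()]) followed by clamping of
#' negative branch lengths (set to zero, the deficit pushed onto the adjacent
#' descendant edges so path lengths through the node are preserved) and
#' midpoint rooting. NJ output is unrooted; midpoint rooting is deterministic
#' and parameter-free, and the rooting within a family hardly matters
#' downstream because age calibration discards the substitution-scale branch
#' lengths anyway. Two taxa produce a cherry splitting their distance evenly.
#'
#' @param D symmetric distance matrix (>= 2 taxa) with zero diagonal.
#' @return rooted [ape::phylo] tree.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 2) stop_metadiv("need at least two taxa")
  if (max(abs(D - t(D))) > 1e-12) stop_metadiv("distance matrix is not symmetric")
  if (nrow(D) == 2) {
    h <- D[1, 2] / 2
    txt <- sprintf("(%s:%.10g,%s:%.10g);", rownames(D)[1], h, rownames(D)[2], h)
    return(ape::read.tree(text = txt))
  }
  tr <- ape::nj(stats::as.dist(D))
  tr <- clamp_negative_edges(tr)
  tr <- phangorn::midpoint(tr)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# set negative edges to zero and move the deficit to the adjacent descendant
# edges, preserving path lengths through the clamped node
clamp_negative_edges <- function(tree) {
  ntip <- length(tree$tip.label)
  repeat {
    neg <- which(tree$edge.length < 0)
    if (!length(neg)) break
    e <- neg[1]
    deficit <- -tree$edge.length[e]
    tree$edge.length[e] <- 0
    child <- tree$edge[e, 2]
    if (child > ntip) {
      down <- which(tree$edge[, 1] == child)
      tree$edge.length[down] <- tree$edge.length[down] + deficit
    }
  }
  tree
}

# resolve a family name to a node in the backbone: prefer an internal node
# carrying the label, else the tip with that name; ambiguity is an error
resolve_family_node <- function(tree, family) {
  ntip <- length(tree$tip.label)
  hits_int <- if (!is.null(tree$node.label)) which(tree$node.label == family) + ntip else integer(0)
  hits_tip <- which(tree$tip.label == family)
  if (length(hits_int) + length(hits_tip) > 1) {
    stop_metadiv("family label '", family, "' is ambiguous in the backbone")
  }
  if (length(hits_int)) return(c(node = hits_int, type = 1L))
  if (length(hits_tip)) return(c(node = hits_tip, type = 0L))
  NULL
}

#' Graft family subtrees onto the backbone
#'
#' Each family's backbone tip is replaced by the rooted subtree of its OTUs
#' (via [ape::bind.tree()]); a single-OTU family simply renames the family tip
#' to the OTU id. Families absent from the backbone are skipped and reported,
#' never silently dropped. Branch lengths are placeholders at this stage --
#' grafting an ultrametric backbone with substitution-scale subtrees
#' necessarily skews depths, which the subsequent age calibration repairs.
#'
#' @param backbone dated family-level backbone tree ([ape::phylo]); families
#'   appear as tips (or labelled internal nodes).
#' @param subtrees named list, family -> rooted [ape::phylo] subtree whose
#'   tips are OTU ids, or a single OTU id (character) for 1-OTU families.
#' @param taxonomy optional data.frame (otu_id, family, order) used to verify
#'   that every grafted OTU belongs to the family it is grafted under.
#' @return list of class `graft_result`: `tree`, `report` (data.frame:
#'   family, status, n_otus), `skipped` (character).
#' @export
graft_subtrees <- function(backbone, subtrees, taxonomy = NULL) {
  stopifnot(inherits(backbone, "phylo"))
  if (is.null(names(subtrees)) || anyDuplicated(names(subtrees))) {
    stop_metadiv("subtrees must be a uniquely named list (family -> subtree)")
  }
  tree <- backbone
  report <- list()
  for (fam in sort(names(subtrees))) {
    sub <- subtrees[[fam]]
    tips <- if (inherits(sub, "phylo")) sub$tip.label else as.character(sub)
    if (!is.null(taxonomy)) {
      known <- taxonomy$family[match(tips, taxonomy$otu_id)]
      wrong <- tips[!is.na(known) & known != fam]
      if (length(wrong)) {
        stop_metadiv("OTU(s) grafted under '", fam, "' but assigned elsewhere: ",
                     paste(wrong, collapse = ", "))
      }
    }
    clash <- intersect(tips, tree$tip.label)
    if (length(clash)) {
      stop_metadiv("subtree tip label(s) already present in the tree: ",
                   paste(clash, collapse = ", "))
    }
    loc <- resolve_family_node(tree, fam)
    if (is.null(loc)) {
      report[[fam]] <- data.frame(family = fam, status = "skipped_not_in_backbone",
                                  n_otus = length(tips), stringsAsFactors = FALSE)
      next
    }
    if (loc[["type"]] == 0L) {
      if (length(tips) == 1L && !inherits(sub, "phylo")) {
        tree$tip.label[loc[["node"]]] <- tips
      } else {
        sub2 <- sub
        sub2$root.edge <- 0
        tree <- ape::bind.tree(tree, sub2, where = loc[["node"]])
      }
      status <- "grafted"
    } else {
      if (!inherits(sub, "phylo")) stop_metadiv("cannot graft a bare OTU id at internal node '", fam, "'")
      sub2 <- sub
      sub2$root.edge <- 0
      tree <- ape::bind.tree(tree, sub2, where = loc[["node"]])
      status <- "grafted_at_internal"
    }
    report[[fam]] <- data.frame(family = fam, status = status,
                                n_otus = length(tips), stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, report)
  rownames(report) <- NULL
  structure(list(tree = tree, report = report,
                 skipped = report$family[grepl("skipped", report$status)]),
            class = "graft_result")
}

#' @export
print.graft_result <- function(x, ...) {
  cat("Grafted", sum(!grepl("skipped", x$report$status)), "families;",
      length(x$skipped), "skipped\n")
  invisible(x)
}

#' Insert a missing family as sister to a backbone family
#'
#' Used when a family is absent from the backbone but the literature provides
#' a sister family already present: the new family tip is attached so the two
#' form a cherry, splitting the sister's terminal edge at its midpoint. The
#' placement is a pre-calibration placeholder; node ages are fixed later by
#' [calibrate_ages()].
#'
#' @param backbone [ape::phylo] tree.
#' @param new_family family to insert (must be absent).
#' @param sister_family existing tip the new family is sister to.
#' @return tree with the new tip.
#' @export
insert_family_as_sister <- function(backbone, new_family, sister_family) {
  stopifnot(inherits(backbone, "phylo"))
  if (new_family %in% backbone$tip.label) {
    stop_metadiv("family '", new_family, "' is already present")
  }
  w <- which(backbone$tip.label == sister_family)
  if (length(w) != 1) stop_metadiv("sister family '", sister_family, "' not found (or ambiguous)")
  el <- backbone$edge.length[backbone$edge[, 2] == w]
  pos <- el / 2
  phytools::bind.tip(backbone, new_family, edge.length = pos, where = w,
                     position = pos)
}

#' bladj-style node age calibration
#'
#' Given fixed ages for a subset of labelled internal nodes (tips are fixed at
#' age 0), every uncalibrated node receives an age by even spacing along the
#' node path between its nearest calibrated ancestor and its nearest
#' calibrated (or tip) descendant, processing nodes root-to-tip. Branch
#' lengths are recomputed as the age differences; the incoming branch lengths
#' (e.g. NJ substitution distances) are discarded. Calibration is idempotent
#' and leaves calibrated nodes untouched.
#'
#' If the root itself is uncalibrated its age defaults to 1.05 x the oldest
#' calibration (with a warning): a root set exactly to the oldest calibrated
#' age would violate the strict parent-older-than-child ordering the dated
#' tree must satisfy.
#'
#' @param tree [ape::phylo] with internal `node.label`s resolvable against
#'   `calibrations`.
#' @param calibrations named numeric vector, node label -> age (time before
#'   present, same unit as the backbone, e.g. Myr).
#' @return tree with branch lengths in age units; attribute `"node_ages"`
#'   holds the age of every node (tips first, ape numbering).
#' @export
calibrate_ages <- function(tree, calibrations) {
  stopifnot(inherits(tree, "phylo"))
  if (!length(calibrations)) stop_metadiv("no calibrations given")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  root <- ntip + 1L
  labs <- tree$node.label %||% rep(NA_character_, nnode)
  node_of <- function(lbl) {
    j <- which(labs == lbl)
    if (length(j) > 1) stop_metadiv("calibration label '", lbl, "' is ambiguous")
    if (length(j) == 1) ntip + j else NA_integer_
  }
  cal_nodes <- vapply(names(calibrations), node_of, integer(1))
  unresolved <- names(calibrations)[is.na(cal_nodes)]
  if (length(unresolved)) {
    stop_metadiv("calibration label(s) absent from the tree: ",
                 paste(unresolved, collapse = ", "))
  }
  ages <- rep(NA_real_, ntip + nnode)
  ages[seq_len(ntip)] <- 0
  fixed <- rep(FALSE, ntip + nnode)
  ages[cal_nodes] <- as.numeric(calibrations)
  fixed[cal_nodes] <- TRUE

  tree2 <- ape::reorder.phylo(tree, "cladewise")
  edge <- tree2$edge
  children <- split(edge[, 2], edge[, 1])

  # fixed-vs-fixed consistency: walk up from each calibrated node
  parent_of <- integer(ntip + nnode)
  parent_of[edge[, 2]] <- edge[, 1]
  for (v in cal_nodes) {
    u <- v
    while (u != root) {
      u <- parent_of[u]
      if (fixed[u] && ages[u] <= ages[v]) {
        stop_metadiv("calibration conflict: ancestor '", labs[u - ntip],
                     "' (", ages[u], ") not older than descendant '",
                     labs[v - ntip], "' (", ages[v], ")")
      }
    }
  }

  if (!fixed[root]) {
    ages[root] <- 1.05 * max(as.numeric(calibrations))
    fixed[root] <- TRUE
    warning("root not calibrated; set to 1.05 x the oldest calibration (",
            signif(ages[root], 6), ")", call. = FALSE)
  }

  # max fixed (calibrated or tip) descendant age below every node, postorder
  maxfix <- rep(0, ntip + nnode)
  for (e in rev(seq_len(nrow(edge)))) {
    par <- edge[e, 1]; ch <- edge[e, 2]
    contrib <- if (fixed[ch] || ch <= ntip) ages[ch] else maxfix[ch]
    maxfix[par] <- max(maxfix[par], contrib)
  }

  # nearest fixed/tip descendant: level-order search returning (steps, age)
  nearest_fixed_down <- function(v) {
    level <- children[[as.character(v)]]
    steps <- 1L
    repeat {
      stops <- level[fixed[level] | level <= ntip]
      if (length(stops)) return(c(steps = steps, age = max(ages[stops])))
      level <- unlist(children[as.character(level)], use.names = FALSE)
      steps <- steps + 1L
    }
  }

  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1]; ch <- edge[e, 2]
    if (ch <= ntip) next
    if (fixed[ch]) {
      if (ages[ch] >= ages[par] - 1e-9) {
        stop_metadiv("calibration conflict at node '", labs[ch - ntip],
                     "': age ", ages[ch], " >= parent age ", signif(ages[par], 8))
      }
      next
    }
    nf <- nearest_fixed_down(ch)
    cand <- nf[["age"]] + (ages[par] - nf[["age"]]) * nf[["steps"]] / (nf[["steps"]] + 1)
    if (cand <= maxfix[ch] + 1e-12) cand <- (ages[par] + maxfix[ch]) / 2
    ages[ch] <- cand
  }

  tree2$edge.length <- ages[edge[, 1]] - ages[edge[, 2]]
  if (any(tree2$edge.length <= -1e-9)) stop_metadiv("internal error: negative age difference")
  attr(tree2, "node_ages") <- ages
  tree2
}

#' Equalize root-to-tip path lengths
#'
#' Adjusts terminal branch lengths so every root-to-tip depth equals the
#' maximum depth, the final safety step making the calibrated tree exactly
#' ultrametric for the phylogenetic-diversity machinery. If any tip requires
#' an adjustment larger than `tol` the tree is considered mis-calibrated and
#' an error is raised.
#'
#' @param tree calibrated [ape::phylo].
#' @param tol largest permissible per-tip adjustment (default `Inf`).
#' @return ultrametric tree; attribute `"max_adjustment"` reports the largest
#'   correction applied.
#' @export
force_ultrametric <- function(tree, tol = Inf) {
  stopifnot(inherits(tree, "phylo"))
  depths <- ape::node.depth.edgelength(tree)
  ntip <- length(tree$tip.label)
  tipd <- depths[seq_len(ntip)]
  target <- max(tipd)
  adj <- target - tipd
  if (max(adj) > tol) {
    stop_metadiv("tip-height adjustment ", signif(max(adj), 6),
                 " exceeds tolerance ", tol, " (tree badly mis-calibrated)")
  }
  term <- match(seq_len(ntip), tree$edge[, 2])
  tree$edge.length[term] <- tree$edge.length[term] + adj
  attr(tree, "max_adjustment") <- max(adj)
  tree
}

#' Assemble the dated mega-tree in one call
#'
#' Runs the whole tree stage: JC69 + NJ subtrees per family alignment,
#' optional sister-family insertions, grafting, age calibration and
#' tip-height equalization.
#'
#' @param backbone family-level backbone tree.
#' @param alignments named list, family -> named character vector of aligned
#'   sequences (1-OTU families may map to a bare OTU id).
#' @param taxonomy data.frame (otu_id, family, order).
#' @param calibrations named ages, see [calibrate_ages()].
#' @param sisters optional data.frame (new_family, sister_family) applied
#'   before grafting.
#' @param tol passed to [force_ultrametric()].
#' @return list: `tree` (dated ultrametric mega-tree), `report` (grafting
#'   report), `skipped`.
#' @export
build_megatree <- function(backbone, alignments, taxonomy, calibrations,
                           sisters = NULL, tol = Inf) {
  if (!is.null(sisters)) {
    for (i in seq_len(nrow(sisters))) {
      backbone <- insert_family_as_sister(backbone, sisters$new_family[i],
                                          sisters$sister_family[i])
    }
  }
  subtrees <- lapply(alignments, function(a) {
    if (length(a) == 1L) names(a) %||% as.character(a)
    else nj_tree(jc69_distances(a))
  })
  gr <- graft_subtrees(backbone, subtrees, taxonomy)
  cal <- calibrate_ages(gr$tree, calibrations)
  list(tree = force_ultrametric(cal, tol = tol), report = gr$report,
       skipped = gr$skipped)
}
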