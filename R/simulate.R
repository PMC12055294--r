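# Seeded generators for every input the pipeline consumes, with known ground
# truth so that estimator-recovery tests have an oracle to compare against.
# Every generator is a pure function of its seed.

#' Simulate community relative abundances
#'
#' @param S number of species (OTUs).
#' @param model `"equal"`, `"geometric"` (proportions proportional to
#'   `ratio^(0:(S-1))`) or `"lognormal"` (log-abundances N(0, sigma^2), the
#'   usual skewed rank-abundance shape of insect communities).
#' @param ratio geometric decay in (0, 1].
#' @param sigma lognormal shape parameter (> 0).
#' @param seed RNG seed (used by the lognormal model).
#' @param ids species identifiers (default OTU0001...).
#' @return named vector of strictly positive proportions summing to 1.
#' @export
simulate_community <- function(S, model = c("equal", "geometric", "lognormal"),
                               ratio = 0.9, sigma = 1.5, seed = NULL,
                               ids = sprintf("OTU%04d", seq_len(S))) {
  model <- match.arg(model)
  if (S < 1) stop_metadiv("S must be >= 1")
  p <- switch(model,
    equal = rep(1 / S, S),
    geometric = {
      if (!(ratio > 0 && ratio <= 1)) stop_metadiv("ratio must be in (0, 1]")
      w <- ratio^(0:(S - 1)); w / sum(w)
    },
    lognormal = {
      if (sigma <= 0) stop_metadiv("sigma must be > 0")
      w <- with_seed(seed, rlnorm(S, meanlog = 0, sdlog = sigma))
      w / sum(w)
    })
  setNames(p, ids)
}

#' Multinomial read sampling
#'
#' Draws `n` reads from the community proportions, emulating sequencing a
#' sample to a given depth.
#'
#' @param proportions named community proportions.
#' @param n sequencing depth (reads, >= 1).
#' @param seed RNG seed.
#' @return named integer count vector (zeros retained).
#' @export
simulate_reads <- function(proportions, n, seed = NULL) {
  if (n < 1) stop_metadiv("depth n must be >= 1")
  counts <- with_seed(seed, drop(rmultinom(1, size = n, prob = proportions)))
  setNames(as.integer(counts), names(proportions))
}

#' Assemble a community matrix from per-sample count vectors
#'
#' @param samples named list of named count vectors.
#' @return integer matrix, rows = samples, columns = union of OTU ids.
#' @export
build_table <- function(samples) {
  if (is.null(names(samples))) names(samples) <- sprintf("S%03d", seq_along(samples))
  otus <- sort(unique(unlist(lapply(samples, names))))
  tab <- matrix(0L, length(samples), length(otus),
                dimnames = list(names(samples), otus))
  for (s in names(samples)) {
    x <- samples[[s]]
    tab[s, names(x)] <- as.integer(x)
  }
  validate_otu_table(tab)
}

#' Inject sequencing-error pseudo-OTUs
#'
#' Adds `k` spurious OTUs with count 1 each (ids disjoint from the real ones),
#' the exact violation the singleton filter targets: the singleton count f1
#' rises by k, n rises by k, and all other frequency counts are untouched.
#'
#' @param counts named count vector for one sample.
#' @param k number of pseudo-singletons (>= 0).
#' @param seed unused by the default deterministic id scheme, accepted for
#'   interface symmetry.
#' @param prefix id prefix for the injected OTUs.
#' @return extended count vector.
#' @export
inject_errors <- function(counts, k, seed = NULL, prefix = "ERR") {
  if (k < 0) stop_metadiv("k must be >= 0")
  if (k == 0) return(counts)
  ids <- sprintf("%s%04d", prefix, seq_len(k))
  clash <- intersect(ids, names(counts))
  if (length(clash)) stop_metadiv("error ids clash with real OTU ids")
  c(counts, setNames(rep(1L, k), ids))
}

#' Simulate a dated ultrametric family backbone
#'
#' A random coalescent tree rescaled to the requested depth, with tips
#' labelled as families, internal nodes labelled `nodeK`, and the true node
#' ages returned as a calibration set (tips age 0).
#'
#' @param n_families number of family tips (>= 2).
#' @param depth root age (time units, e.g. Myr).
#' @param seed RNG seed.
#' @return list: `tree` (ultrametric, node labels set), `ages` (named ages of
#'   internal nodes), `calibrations` (same, usable by [calibrate_ages()]).
#' @export
simulate_backbone <- function(n_families = 12, depth = 300, seed = NULL) {
  if (n_families < 2) stop_metadiv("need >= 2 families")
  tr <- with_seed(seed, ape::rcoal(n_families,
                                   tip.label = sprintf("Fam%02d", seq_len(n_families))))
  d <- max(ape::node.depth.edgelength(tr)[seq_len(n_families)])
  tr$edge.length <- tr$edge.length * depth / d
  tr$node.label <- sprintf("node%d", seq_len(tr$Nnode))
  depths <- ape::node.depth.edgelength(tr)
  ages <- depth - depths[(n_families + 1):(n_families + tr$Nnode)]
  names(ages) <- tr$node.label
  list(tree = tr, ages = ages, calibrations = ages)
}

#' Evolve aligned sequences on a tree under Jukes-Cantor
#'
#' Site-independent JC substitution with per-edge substitution probability
#' determined by branch length x rate (via [phangorn::simSeq()]); the
#' returned alignment is gap-free, so the JC distance + neighbour-joining
#' rebuild is an honest end-to-end oracle for the tree stage.
#'
#' @param tree [ape::phylo] with branch lengths.
#' @param length alignment length in sites (>= 1).
#' @param rate substitutions per site per unit branch length (>= 0).
#' @param seed RNG seed.
#' @return named character vector of equal-length sequences.
#' @export
evolve_sequences <- function(tree, length = 500, rate = 1, seed = NULL) {
  if (length < 1) stop_metadiv("alignment length must be >= 1")
  if (rate < 0) stop_metadiv("rate must be >= 0")
  if (rate == 0) {
    base <- with_seed(seed, paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                                  collapse = ""))
    return(setNames(rep(base, length(tree$tip.label)), tree$tip.label))
  }
  dat <- with_seed(seed, phangorn::simSeq(tree, l = length, rate = rate, type = "DNA"))
  M <- toupper(as.character(dat))
  setNames(apply(M, 1, paste, collapse = ""), rownames(M))
}

#' Simulate a complete synthetic study
#'
#' Generates every input of the workflow with known ground truth: a dated
#' family backbone, within-family subtrees and JC-evolved barcode alignments,
#' a skewed (lognormal) community over all OTUs, multinomial read sampling at
#' uneven depths for two habitat groups drawing on partially distinct species
#' pools, spurious singleton injection, taxonomy, node-age calibrations and a
#' small environmental table.
#'
#' @param n_families families on the backbone.
#' @param otus_per_family OTUs per family.
#' @param n_samples total samples (split evenly into habitat groups A/B).
#' @param depth_range sequencing depth range (uniform per sample).
#' @param k_errors spurious singletons injected per sample.
#' @param sigma lognormal shape of the community.
#' @param backbone_depth root age of the backbone (Myr).
#' @param family_depth crown age of each family subtree (Myr).
#' @param rate substitution rate for barcode evolution (per site per Myr).
#' @param seq_length barcode alignment length.
#' @param seed root seed; all stage seeds derive from it.
#' @return list: `table` (with injected errors), `table_clean`, `taxonomy`,
#'   `backbone`, `alignments`, `subtrees` (true family subtrees),
#'   `calibrations`, `env`, `truth` (proportions, group pools, k_errors,
#'   depths).
#' @export
simulate_dataset <- function(n_families = 8, otus_per_family = 4,
                             n_samples = 12, depth_range = c(1500, 3000),
                             k_errors = 25, sigma = 1.5,
                             backbone_depth = 300, family_depth = 40,
                             rate = 0.002, seq_length = 500, seed = 1) {
  bb <- simulate_backbone(n_families, depth = backbone_depth, seed = seed)
  families <- bb$tree$tip.label
  otu_ids <- as.vector(vapply(seq_along(families), function(i) {
    sprintf("%s_OTU%02d", families[i], seq_len(otus_per_family))
  }, character(otus_per_family)))
  taxonomy <- data.frame(
    otu_id = otu_ids,
    family = rep(families, each = otus_per_family),
    order = rep(sprintf("Order%02d", (seq_along(families) + 1) %/% 2),
                each = otus_per_family),
    stringsAsFactors = FALSE)

  subtrees <- list(); alignments <- list()
  for (i in seq_along(families)) {
    fam <- families[i]
    tips <- taxonomy$otu_id[taxonomy$family == fam]
    st <- with_seed(seed + 100 + i, ape::rcoal(length(tips), tip.label = tips))
    d <- max(ape::node.depth.edgelength(st)[seq_along(tips)])
    st$edge.length <- st$edge.length * family_depth / d
    subtrees[[fam]] <- st
    alignments[[fam]] <- evolve_sequences(st, length = seq_length, rate = rate,
                                          seed = seed + 200 + i)
  }

  props <- simulate_community(length(otu_ids), model = "lognormal",
                              sigma = sigma, seed = seed + 300, ids = otu_ids)
  # two habitat groups with partially distinct pools (block structure for beta)
  half <- ceiling(length(otu_ids) / 2)
  poolA <- otu_ids[seq_len(half + floor(half / 2))]
  poolB <- otu_ids[(half - floor(half / 2) + 1):length(otu_ids)]
  renorm <- function(ids) { p <- props[ids]; p / sum(p) }
  group <- rep(c("A", "B"), length.out = n_samples)
  depths <- with_seed(seed + 400,
                      sample(seq(depth_range[1], depth_range[2]), n_samples,
                             replace = TRUE))
  samples <- list()
  for (s in seq_len(n_samples)) {
    pool <- if (group[s] == "A") poolA else poolB
    x <- simulate_reads(renorm(pool), depths[s], seed = seed + 500 + s)
    samples[[sprintf("S%03d", s)]] <- x[x > 0]
  }
  table_clean <- build_table(samples)
  with_err <- lapply(seq_along(samples), function(s) {
    inject_errors(samples[[s]], k_errors, prefix = sprintf("ERR_S%03d_", s))
  })
  names(with_err) <- names(samples)
  table <- build_table(with_err)

  env <- data.frame(
    row.names = names(samples),
    habitat = factor(group),
    day = with_seed(seed + 600, round(runif(n_samples, 120, 240))),
    temperature = with_seed(seed + 601, round(rnorm(n_samples, 15, 3), 1)),
    x_coord = with_seed(seed + 602, round(runif(n_samples, 0, 1e4))),
    y_coord = with_seed(seed + 603, round(runif(n_samples, 0, 1e4))))

  list(table = table, table_clean = table_clean, taxonomy = taxonomy,
       backbone = bb$tree, alignments = alignments, subtrees = subtrees,
       calibrations = bb$calibrations, env = env,
       truth = list(proportions = props, poolA = poolA, poolB = poolB,
                    k_errors = k_errors, depths = setNames(depths, names(samples)),
                    group = setNames(group, names(samples))))
}
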