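#' Simulation configuration for ITS-like alignments
#'
#' Defines the statistical structure the analysis assumes: an
#' ITS1-5.8S-ITS2 amplicon whose 5.8S is highly conserved (slow rate
#' multiplier) while the flanking spacers are variable, evolved along a tree
#' under the K2P substitution model with transition/transversion rate ratio
#' `kappa`, with optional spacer-only indels.
#'
#' @param n_taxa number of taxa (used when `tree` is `NULL`: a random
#'   Yule tree is drawn).
#' @param tree fixed tree: Newick string or [ape::phylo]; `NULL` for Yule.
#' @param kappa transition/transversion *rate* ratio (alpha/beta), > 0.
#' @param region_sites sites per region `c(its1, r58s, its2)`.
#' @param region_rates rate multipliers `c(its1, r58s, its2)`; the default
#'   makes the 5.8S five-fold slower than the spacers.
#' @param indel_rate expected indel events per spacer per unit branch
#'   length (0 disables; indels never touch the 5.8S).
#' @param indel_mean_len mean of the geometric indel length distribution.
#' @param gc GC bias of the root sequence composition.
#' @param total_depth when a Yule tree is drawn it is rescaled so the mean
#'   root-to-tip path equals this expected substitutions/site.
#' @param seed integer seed (required: no wall-clock seeding).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_taxa = 6L, tree = NULL, kappa = 2,
                       region_sites = c(its1 = 230L, r58s = 163L, its2 = 247L),
                       region_rates = c(its1 = 1.5, r58s = 0.3, its2 = 1.2),
                       indel_rate = 0, indel_mean_len = 2, gc = 0.53,
                       total_depth = 0.05, seed) {
  fail_if(missing(seed), "seed is required")
  fail_if(length(region_sites) != 3L || length(region_rates) != 3L,
          "region_sites and region_rates must have 3 entries (ITS1, 5.8S, ITS2)")
  names(region_sites) <- names(region_rates) <- c("its1", "r58s", "its2")
  region_sites <- as.integer(region_sites)
  names(region_sites) <- c("its1", "r58s", "its2")
  fail_if(any(region_sites <= 0L), "region sites must be > 0")
  fail_if(any(region_rates < 0) || kappa <= 0 || indel_rate < 0,
          "rates must be >= 0 and kappa > 0")
  structure(list(n_taxa = as.integer(n_taxa), tree = tree, kappa = kappa,
                 region_sites = region_sites, region_rates = region_rates,
                 indel_rate = indel_rate, indel_mean_len = indel_mean_len,
                 gc = gc, total_depth = total_depth, seed = as.integer(seed)),
            class = "sim_config")
}

#' Read a simulation configuration from a key-value (DCF) file
#'
#' Fields mirror the [sim_config()] arguments; vector-valued fields
#' (`region_sites`, `region_rates`) are comma-separated, and `tree` holds a
#' Newick string. Unknown fields error.
#'
#' @param path file in Debian-control (key: value) format.
#' @return a `sim_config`.
#' @export
sim_config_from_file <- function(path) {
  fail_if(!file.exists(path), "file not found: %s", path)
  dcf <- read.dcf(path)
  fields <- setNames(as.list(dcf[1, ]), colnames(dcf))
  known <- names(formals(sim_config))
  bad <- setdiff(names(fields), known)
  fail_if(length(bad) > 0L, "unknown config field(s): %s",
          paste(bad, collapse = ", "))
  num_vec <- function(x) as.numeric(strsplit(x, ",")[[1]])
  args <- list()
  for (nm in names(fields)) {
    args[[nm]] <- switch(nm,
      tree = fields[[nm]],
      n_taxa = , seed = as.integer(fields[[nm]]),
      region_sites = , region_rates = num_vec(fields[[nm]]),
      as.numeric(fields[[nm]]))
  }
  do.call(sim_config, args)
}

## K80 transition probabilities for branch length d (expected subs/site)
## and rate ratio kappa = alpha/beta: returns c(p_same, p_ts, p_tv_each).
k80_probs <- function(d, kappa) {
  bt <- d / (kappa + 2)
  at <- kappa * bt
  e1 <- exp(-4 * bt)
  e2 <- exp(-2 * (at + bt))
  p_tv <- 0.25 - 0.25 * e1
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  c(same = 1 - p_ts - 2 * p_tv, ts = p_ts, tv = p_tv)
}

TS_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")
TV_PARTNERS <- list(A = c("C", "T"), G = c("C", "T"),
                    C = c("A", "G"), T = c("A", "G"))

## Evolve a base vector along one branch under K80.
evolve_branch <- function(seq, d, kappa) {
  if (d <= 0) return(seq)
  pr <- k80_probs(d, kappa)
  u <- stats::runif(length(seq))
  ts <- u < pr["ts"]
  tv <- !ts & u < pr["ts"] + 2 * pr["tv"]
  out <- seq
  if (any(ts)) out[ts] <- TS_PARTNER[seq[ts]]
  if (any(tv)) {
    which_tv <- which(tv)
    pickB <- stats::runif(length(which_tv)) < 0.5
    out[which_tv] <- vapply(seq_along(which_tv), function(k) {
      TV_PARTNERS[[seq[which_tv[k]]]][if (pickB[k]) 2L else 1L]
    }, character(1))
  }
  out
}

#' Simulate an ITS alignment along a tree
#'
#' Draws a root sequence with the configured GC bias, evolves it along the
#' tree under K2P with per-region rate multipliers, and (optionally)
#' applies geometric-length indels to the spacers of each tip, leaving the
#' 5.8S untouched. Deterministic given the config seed.
#'
#' @param config a [sim_config()].
#' @return list: `tree` (the true [ape::phylo]), `records` (partitioned
#'   [its_record()]s), `alignment` (`its_alignment` of the true gap-free
#'   homology when `indel_rate = 0`, else `NULL`), `ref58s` (the root 5.8S,
#'   usable as the anchor reference).
#' @export
simulate_alignment <- function(config) {
  fail_if(!inherits(config, "sim_config"), "config must be a sim_config")
  set.seed(config$seed)
  tree <- config$tree
  if (is.null(tree)) {
    tree <- ape::rphylo(config$n_taxa, birth = 1, death = 0)  # Yule
    depths <- ape::node.depth.edgelength(tree)[seq_len(config$n_taxa)]
    tree$edge.length <- tree$edge.length * (config$total_depth / mean(depths))
  } else if (is.character(tree)) {
    tree <- tryCatch(ape::read.tree(text = tree),
                     error = function(e) NULL)
    fail_if(is.null(tree), "invalid Newick tree")
  }
  fail_if(is.null(tree$edge.length), "tree must have branch lengths")
  sites <- config$region_sites
  L <- sum(sites)
  region_of <- rep(c("its1", "r58s", "its2"), sites)
  p_gc <- config$gc
  root <- sample(BASES, L, TRUE,
                 prob = c((1 - p_gc) / 2, p_gc / 2, p_gc / 2, (1 - p_gc) / 2))
  ntip <- length(tree$tip.label)
  seqs <- vector("list", ntip + tree$Nnode)
  ord <- ape::reorder.phylo(tree, "cladewise")   # parents before children
  rootnode <- ntip + 1L
  seqs[[rootnode]] <- root
  for (e in seq_len(nrow(ord$edge))) {
    p <- ord$edge[e, 1L]; ch <- ord$edge[e, 2L]
    d <- ord$edge.length[e]
    seq <- seqs[[p]]
    ## per-region rate multipliers: evolve region chunks at scaled lengths
    out <- seq
    for (rg in c("its1", "r58s", "its2")) {
      idx <- which(region_of == rg)
      out[idx] <- evolve_branch(seq[idx], d * config$region_rates[[rg]],
                                config$kappa)
    }
    seqs[[ch]] <- out
  }
  tip_seqs <- seqs[seq_len(ntip)]
  names(tip_seqs) <- tree$tip.label
  aln <- NULL
  if (config$indel_rate == 0) {
    mat <- do.call(rbind, tip_seqs)
    rownames(mat) <- tree$tip.label
    aln <- its_alignment(mat)
  }
  records <- vector("list", ntip)
  for (i in seq_len(ntip)) {
    s <- tip_seqs[[i]]
    lens <- sites
    if (config$indel_rate > 0) {
      res <- apply_spacer_indels(s, region_of, config)
      s <- res$seq; lens <- res$lens
    }
    rec <- its_record(tree$tip.label[i], s)
    rec$regions <- region_partition(c(0L, lens[1]),
                                    c(lens[1], lens[1] + lens[2]),
                                    c(lens[1] + lens[2], sum(lens)))
    records[[i]] <- rec
  }
  ref58s <- root[region_of == "r58s"]
  list(tree = tree, records = records, alignment = aln, ref58s = ref58s)
}

## Insertions/deletions restricted to the spacers; geometric lengths.
## Expected number of events per spacer is indel_rate (per tip).
apply_spacer_indels <- function(seq, region_of, config) {
  pieces <- split(seq, factor(region_of, levels = c("its1", "r58s", "its2")))
  for (rg in c("its1", "its2")) {
    x <- pieces[[rg]]
    n_events <- stats::rpois(1, config$indel_rate)
    for (k in seq_len(n_events)) {
      len <- stats::rgeom(1, 1 / config$indel_mean_len) + 1L
      if (stats::runif(1) < 0.5 && length(x) > len + 10L) {      # deletion
        at <- sample.int(length(x) - len, 1L)
        x <- x[-(at:(at + len - 1L))]
      } else {                                                    # insertion
        at <- sample.int(length(x), 1L)
        ins <- sample(BASES, len, TRUE)
        x <- append(x, ins, after = at)
      }
    }
    pieces[[rg]] <- x
  }
  list(seq = unlist(pieces, use.names = FALSE),
       lens = vapply(pieces, length, integer(1)))
}

#' Construct four-helix ITS2-like structures with prescribed features
#'
#' Builds dot-bracket structures realizing requested stem lengths and loop
#' counts exactly, and helix angles realized on an equal-arc central loop of
#' `grid` positions (angle resolution `360/grid` degrees; requested angles
#' are snapped to the grid). The emitted structure and its intended feature
#' vector are mutual inverses under [feature_vector()].
#'
#' @param n number of structures.
#' @param angle_mean,angle_sd per-helix means/sds of angles (degrees,
#'   helix I is the 0-degree anchor).
#' @param stem_mean,stem_sd per-helix stem-length (bp) means/sds.
#' @param loop_mean,loop_sd per-helix loop-count means/sds.
#' @param grid equal-arc positions on the central loop (default 72: 5
#'   degree resolution).
#' @param seed integer seed.
#' @return list: `structures` (named list of `secondary_structure`),
#'   `features` (n x 12 matrix of realized feature vectors).
#' @export
simulate_structures <- function(n,
                                angle_mean = c(0, 90, 180, 270), angle_sd = 10,
                                stem_mean = c(9, 6, 12, 5), stem_sd = 1.5,
                                loop_mean = c(2, 2, 3, 1), loop_sd = 0.7,
                                grid = 72L, seed) {
  fail_if(missing(seed), "seed is required")
  fail_if(n < 1L, "n must be >= 1")
  fail_if(grid < 8L, "grid too small for four helices")
  set.seed(seed)
  structures <- vector("list", n)
  feats <- matrix(0, n, 12)
  colnames(feats) <- c(paste0("angle_", c("I", "II", "III", "IV")),
                       paste0("len_", c("I", "II", "III", "IV")),
                       paste0("loops_", c("I", "II", "III", "IV")))
  step <- 360 / grid
  for (s in seq_len(n)) {
    stems <- pmax(1L, round(stats::rnorm(4, stem_mean, stem_sd)))
    loops <- pmax(1L, round(stats::rnorm(4, loop_mean, loop_sd)))
    loops <- pmin(loops, stems)              # each loop needs a stem segment
    ang <- stats::rnorm(4, angle_mean, angle_sd)
    ang[1] <- 0
    k <- round((ang %% 360) / step)
    k[1] <- 0L
    ## enforce strictly increasing attachment positions with room at the end
    for (h in 2:4) k[h] <- max(k[h], k[h - 1L] + 1L)
    fail_if(k[4] > grid - 1L, "infeasible angles: attachments exceed the grid")
    arms <- vapply(1:4, function(h) build_arm(stems[h], loops[h]), character(1))
    spacers <- c(k[2] - k[1] - 1L, k[3] - k[2] - 1L, k[4] - k[3] - 1L,
                 grid - 1L - k[4])
    body <- paste0(arms[1], strrep("A", spacers[1]),
                   arms[2], strrep("A", spacers[2]),
                   arms[3], strrep("A", spacers[3]),
                   arms[4], strrep("A", spacers[4]))
    st <- arm_to_structure(body)
    structures[[s]] <- st
    feats[s, ] <- c(k * step, stems, loops)
  }
  names(structures) <- sprintf("sim%02d", seq_len(n))
  rownames(feats) <- names(structures)
  list(structures = structures, features = feats)
}

## One unbranched arm: `stem` base pairs split into `loops` stacked segments
## separated by single-base 5' bulges, ending in a 3-base hairpin loop.
## Encodes as paired sequence/structure strings (G-C stems, A loops).
build_arm <- function(stem, loops) {
  fail_if(stem < 1L, "stem length must be >= 1")
  fail_if(loops < 1L, "loop count must be >= 1")
  fail_if(loops > stem, "cannot place %d loops on a %d bp stem", loops, stem)
  sizes <- rep(stem %/% loops, loops)
  extra <- stem %% loops
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  inner <- "AAA"                           # terminal hairpin
  for (seg in rev(seq_len(loops))) {
    z <- sizes[seg]
    bulge <- if (seg > 1L) "A" else ""
    inner <- paste0(bulge, strrep("(", z), inner, strrep(")", z))
  }
  inner
}

## Interpret an arm/body template: '(' -> G, ')' -> C, 'A' stays A, giving a
## complementarity-valid sequence for the dot-bracket skeleton.
arm_to_structure <- function(body) {
  chars <- strsplit(body, "")[[1]]
  seq <- ifelse(chars == "(", "G", ifelse(chars == ")", "C", "A"))
  db <- ifelse(chars %in% c("(", ")"), chars, ".")
  secondary_structure(seq_string(seq), seq_string(db), validate = TRUE)
}
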