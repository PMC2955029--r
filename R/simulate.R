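#' Simulate a Yule host tree
#'
#' Pure-birth (Yule) tree conditioned on `n` extant tips, built forward in
#' time from a crown split: with `k` lineages the next speciation waits an
#' exponential time with rate `k * birth_rate`, and a uniformly chosen
#' lineage splits.  After the n-th lineage appears the tree is extended by
#' a final exponential stretch with rate `n * birth_rate`.  Branch lengths
#' are in time units; the tree is rooted, binary and ultrametric.
#'
#' @param n Number of tips (>= 3).
#' @param birth_rate Speciation rate per lineage per time unit.
#' @param seed Optional integer seed.
#' @param labels Tip labels (default `h1..hn`, assigned in lineage order).
#' @return Rooted ultrametric `phylo` tree.
#' @export
simulate_host_tree <- function(n, birth_rate = 1, seed = NULL,
                               labels = paste0("h", seq_len(n))) {
  if (n < 3) stop("need at least 3 tips")
  stopifnot(birth_rate > 0, length(labels) == n)
  with_seed(seed, {
    # node bookkeeping: birth time, split time (NA while active), children
    birth <- c(0, 0); split <- c(NA_real_, NA_real_)
    kids <- list(integer(0), integer(0))
    active <- c(1L, 2L)
    t <- 0
    while (length(active) < n) {
      t <- t + stats::rexp(1, length(active) * birth_rate)
      who <- active[sample.int(length(active), 1)]
      split[who] <- t
      id <- length(birth) + c(1L, 2L)
      birth[id] <- t; split[id] <- NA_real_
      kids[[who]] <- id
      kids[id] <- list(integer(0), integer(0))
      active <- c(setdiff(active, who), id)
    }
    H <- t + stats::rexp(1, n * birth_rate)
    # assign labels to tips at random so labelled topologies are
    # exchangeable (a traversal-order assignment would not be)
    perm <- sample.int(n)
    tip_no <- 0L
    render <- function(id) {
      len <- (if (is.na(split[id])) H else split[id]) - birth[id]
      if (!length(kids[[id]])) {
        tip_no <<- tip_no + 1L
        sprintf("%s:%.10g", labels[perm[tip_no]], len)
      } else {
        sprintf("(%s,%s):%.10g", render(kids[[id]][1]),
                render(kids[[id]][2]), len)
      }
    }
    ape::read.tree(text = sprintf("(%s,%s);", render(1L), render(2L)))
  })
}

# First tip label below a node (representative for event logging).
.rep_tip <- function(tree, node) {
  ntip <- length(tree$tip.label)
  while (node > ntip) node <- tree$edge[tree$edge[, 1] == node, 2][1]
  tree$tip.label[node]
}

#' Simulate a co-phylogenetic scenario on a host tree
#'
#' The parasite (intron) tracks each host lineage one-to-one: it
#' duplicates whenever its host speciates (codivergence), so with no
#' other events the parasite tree is topologically identical to the host
#' tree.  Host-switch events arrive as a Poisson process with rate
#' `switch_rate` per lineage per time unit: the parasite of the sampled
#' (donor) lineage also colonises a recipient lineage drawn uniformly
#' among the other host lineages alive at that moment, replacing the
#' recipient's previous parasite.  Loss events (`loss_rate`, same units)
#' terminate the parasite of the sampled lineage; its descendants are
#' intron-free.  Exact event counts can be forced with
#' `n_switches`/`n_losses` (event locations still drawn uniformly over
#' the tree's branch length).  Parasite leaves inherit their host's
#' label, giving a one-to-one host-intron association over the surviving
#' (intron-bearing) taxa.
#'
#' @param host_tree Rooted ultrametric `phylo` tree (time units), e.g.
#'   from [simulate_host_tree()].
#' @param switch_rate,loss_rate Poisson event rates per lineage-time.
#' @param seed Optional integer seed.
#' @param n_switches,n_losses Force exact event counts (overrides the
#'   rates).
#' @return Object of class `cophylo_scenario`: `host_tree`,
#'   `parasite_tree` (ultrametric, leaves a subset of host labels),
#'   `association` (data frame `host`, `parasite`), `events` (data frame
#'   `type`, `time`, `donor`, `recipient`).
#' @export
simulate_cophylogeny <- function(host_tree, switch_rate = 0, loss_rate = 0,
                                 seed = NULL, n_switches = NULL,
                                 n_losses = NULL) {
  stopifnot(inherits(host_tree, "phylo"))
  if (!ape::is.rooted(host_tree) || !ape::is.binary(host_tree))
    stop("host tree must be rooted and binary")
  ntip <- length(host_tree$tip.label)
  depth <- ape::node.depth.edgelength(host_tree)
  H <- max(depth)
  edge <- host_tree$edge
  with_seed(seed, {
    TL <- sum(host_tree$edge.length)
    draw_points <- function(k) {
      if (k == 0) return(data.frame(edge = integer(0), time = numeric(0)))
      ei <- sample.int(nrow(edge), k, replace = TRUE,
                       prob = host_tree$edge.length)
      data.frame(edge = ei,
                 time = depth[edge[ei, 1]] +
                   stats::runif(k) * host_tree$edge.length[ei])
    }
    ns <- if (!is.null(n_switches)) n_switches
          else stats::rpois(1, switch_rate * TL)
    nl <- if (!is.null(n_losses)) n_losses
          else stats::rpois(1, loss_rate * TL)
    sw <- draw_points(ns); lo <- draw_points(nl)

    ev <- rbind(
      data.frame(type = "speciation", time = depth[(ntip + 1):(ntip +
                   host_tree$Nnode)], edge = NA_integer_,
                 node = (ntip + 1):(ntip + host_tree$Nnode)),
      if (nrow(sw)) data.frame(type = "host_switch", time = sw$time,
                               edge = sw$edge, node = NA_integer_),
      if (nrow(lo)) data.frame(type = "loss", time = lo$time,
                               edge = lo$edge, node = NA_integer_))
    ev <- ev[order(ev$time), , drop = FALSE]

    # parasite node table; node 1 is the stem open at time 0
    p_start <- 0; p_end <- NA_real_; p_kids <- list(integer(0))
    p_label <- NA_character_
    new_pnode <- function(start) {
      p_start[id <- length(p_start) + 1L] <<- start
      p_end[id] <<- NA_real_
      p_kids[[id]] <<- integer(0)
      p_label[id] <<- NA_character_
      id
    }
    # carrier[i]: open parasite node travelling on host edge i (NA = none)
    carrier <- rep(NA_integer_, nrow(edge))
    stem_carrier <- 1L  # parasite on the (zero-length) host stem
    events_log <- list()

    for (i in seq_len(nrow(ev))) {
      e <- ev[i, ]
      if (e$type == "speciation") {
        inc <- which(edge[, 2] == e$node)
        p <- if (length(inc)) carrier[inc] else stem_carrier
        if (is.na(p)) next
        p_end[p] <- e$time
        out <- which(edge[, 1] == e$node)
        for (oe in out) {
          id <- new_pnode(e$time)
          p_kids[[p]] <- c(p_kids[[p]], id)
          carrier[oe] <- id
        }
      } else {
        live <- which(depth[edge[, 1]] < e$time & depth[edge[, 2]] >= e$time)
        if (e$type == "host_switch") {
          p <- carrier[e$edge]
          others <- setdiff(live, e$edge)
          if (is.na(p) || !length(others)) next
          recip <- others[sample.int(length(others), 1)]
          old <- carrier[recip]
          if (!is.na(old)) p_end[old] <- e$time  # replaced; leaves no kids
          p_end[p] <- e$time
          d_id <- new_pnode(e$time)  # continuation on donor
          r_id <- new_pnode(e$time)  # new infection on recipient
          p_kids[[p]] <- c(d_id, r_id)
          carrier[e$edge] <- d_id
          carrier[recip] <- r_id
          events_log[[length(events_log) + 1L]] <- data.frame(
            type = "host_switch", time = e$time,
            donor = .rep_tip(host_tree, edge[e$edge, 2]),
            recipient = .rep_tip(host_tree, edge[recip, 2]))
        } else {  # loss
          p <- carrier[e$edge]
          if (is.na(p)) next
          p_end[p] <- e$time
          carrier[e$edge] <- NA_integer_
          events_log[[length(events_log) + 1L]] <- data.frame(
            type = "loss", time = e$time,
            donor = NA_character_,
            recipient = .rep_tip(host_tree, edge[e$edge, 2]))
        }
      }
    }
    # close surviving branches at the present as labelled parasite leaves
    for (ti in seq_len(ntip)) {
      inc <- which(edge[, 2] == ti)
      p <- carrier[inc]
      if (is.na(p)) next
      p_end[p] <- H
      p_label[p] <- host_tree$tip.label[ti]
    }
    survivors <- !is.na(p_label)
    if (!any(survivors)) stop("empty scenario: all parasites lost")
    if (sum(survivors) < 3)
      stop("degenerate scenario: fewer than 3 surviving parasites")

    alive <- function(id) {
      if (!is.na(p_label[id])) return(TRUE)
      any(vapply(p_kids[[id]], alive, logical(1)))
    }
    render <- function(id, acc) {
      len <- p_end[id] - p_start[id] + acc
      kk <- Filter(alive, p_kids[[id]])
      if (!length(kk)) return(sprintf("%s:%.10g", p_label[id], len))
      if (length(kk) == 1L) return(render(kk[[1]], len))
      sprintf("(%s):%.10g",
              paste(vapply(kk, render, "", acc = 0), collapse = ","), len)
    }
    txt <- render(1L, 0)
    txt <- sub(":[0-9.eE+-]+$", "", txt)
    if (!startsWith(txt, "(")) stop("degenerate scenario: single lineage")
    ptree <- ape::read.tree(text = paste0(txt, ";"))

    structure(list(
      host_tree = host_tree, parasite_tree = ptree,
      association = data.frame(host = ptree$tip.label,
                               parasite = ptree$tip.label),
      events = if (length(events_log)) do.call(rbind, events_log)
               else data.frame(type = character(0), time = numeric(0),
                               donor = character(0),
                               recipient = character(0))),
      class = "cophylo_scenario")
  })
}

#' @export
print.cophylo_dataset <- function(x, ...) {
  cat("Co-phylogenetic dataset:", length(x$host_tree$tip.label), "hosts,",
      length(x$parasite_tree$tip.label), "intron-bearing;",
      sum(x$events$type == "host_switch"), "switch(es),",
      sum(x$events$type == "loss"), "loss(es)\n")
  cat(sprintf("  partitions: %d bp (host) + %d bp (intron)\n",
              ncol(x$aln_host), ncol(x$aln_parasite)))
  invisible(x)
}

#' @export
print.cophylo_scenario <- function(x, ...) {
  cat("Co-phylogenetic scenario:", length(x$host_tree$tip.label), "hosts,",
      length(x$parasite_tree$tip.label), "intron-bearing;",
      sum(x$events$type == "host_switch"), "switch(es),",
      sum(x$events$type == "loss"), "loss(es)\n")
  invisible(x)
}

#' Simulate sequence evolution along a tree
#'
#' Evolves nucleotide sites down a tree under a [subst_model()]: root
#' states are drawn from the stationary frequencies, each site is
#' assigned a rate class (invariant or one of the discrete-gamma
#' categories) and states change along each branch according to the
#' model's transition probabilities.  Branch lengths are interpreted as
#' expected substitutions per site after multiplication by
#' `rate_scale`, the clock factor converting time-trees to
#' substitution-trees.
#'
#' @param tree `phylo` tree with branch lengths.
#' @param model A [subst_model()] (base frequencies default to 1/4 when
#'   unspecified).
#' @param length Number of sites.
#' @param seed Optional integer seed.
#' @param rate_scale Clock factor applied to every branch.
#' @return Alignment matrix over the tree's tips.
#' @export
simulate_alignment <- function(tree, model, length, seed = NULL,
                               rate_scale = 1) {
  stopifnot(length >= 1)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (is.null(model$base_freqs)) model$base_freqs <- rep(0.25, 4)
  eig <- model_eigen(model)
  rc <- rate_classes(model)
  nuc <- c("A", "C", "G", "T")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  tree <- ape::reorder.phylo(tree, "postorder")
  root <- tree$edge[nrow(tree$edge), 1]
  with_seed(seed, {
    cat_of <- sample.int(length(rc$rates), length, replace = TRUE,
                         prob = rc$weights)
    states <- matrix(NA_integer_, nnode, length)
    states[root, ] <- sample.int(4, length, replace = TRUE,
                                 prob = model$base_freqs)
    for (e in rev(seq_len(nrow(tree$edge)))) {  # preorder
      pa <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      t <- tree$edge.length[e] * rate_scale
      for (c in seq_along(rc$rates)) {
        sites <- which(cat_of == c)
        if (!length(sites)) next
        P <- eig$U1 %*% diag(exp(eig$lam * rc$rates[c] * t)) %*% eig$U2
        P[P < 0] <- 0
        P <- P / rowSums(P)
        for (s in 1:4) {
          idx <- sites[states[pa, sites] == s]
          if (!length(idx)) next
          states[ch, idx] <- sample.int(4, base::length(idx),
                                        replace = TRUE, prob = P[s, ])
        }
      }
    }
    out <- matrix(nuc[states[seq_len(ntip), , drop = FALSE]], nrow = ntip)
    rownames(out) <- tree$tip.label
    out
  })
}

#' Insert an intron into a coding sequence
#'
#' Returns `cds[1..site] + intron + cds[(site+1)..]`, the "inserted after
#' position `site`" convention used to name introns by their reference
#' CDS position.
#'
#' @param cds Named length-1 character vector (or string) with the coding
#'   sequence.
#' @param site Reference position after which to insert (`1 <= site <=
#'   nchar(cds)`).
#' @param intron_seq Intron sequence to insert.
#' @return The intron-bearing sequence, named like `cds`.
#' @export
inject_intron <- function(cds, site, intron_seq) {
  s <- unname(cds[[1]])
  n <- nchar(s)
  if (site < 1 || site > n)
    stop("site must be in [1, ", n, "], got ", site)
  out <- paste0(substring(s, 1, site), intron_seq,
                substring(s, site + 1, n))
  if (!is.null(names(cds))) names(out) <- names(cds)[1]
  out
}

#' Simulate a complete co-phylogenetic dataset
#'
#' One call producing everything the co-speciation tests consume: a Yule
#' host tree, a parasite (intron) scenario with the requested amount of
#' horizontal transfer, and one alignment per partition evolved on the
#' respective tree, restricted to the intron-bearing taxa.  Defaults
#' mirror the study conditions of the cox1/intron-723 analysis: partition
#' lengths 630 (cox1) and 1078 (intron) bp, GTR+G+I evolution, and a
#' faster intron clock than the host gene's.
#'
#' @param n_hosts Number of host taxa.
#' @param birth_rate Host speciation rate.
#' @param switch_rate,loss_rate,n_switches,n_losses Passed to
#'   [simulate_cophylogeny()].
#' @param seq_length Length-2 vector: host (cox1) and parasite (intron)
#'   partition lengths in bp.
#' @param model A [subst_model()] used for both partitions.
#' @param host_clock,parasite_clock Substitutions per site per time unit
#'   on each tree.
#' @param seed Integer seed (mandatory for reproducibility).
#' @return Object of class `cophylo_dataset`: the scenario plus `aln_host`
#'   and `aln_parasite` over the intron-bearing taxa, and `links`.
#' @export
simulate_cophylo_dataset <- function(n_hosts = 12, birth_rate = 1,
                                     switch_rate = 0, loss_rate = 0,
                                     n_switches = NULL, n_losses = NULL,
                                     seq_length = c(630, 1078),
                                     model = subst_model(
                                       "GTR",
                                       rates = c(1, 4, 1, 1, 4, 1),
                                       base_freqs = c(0.28, 0.16, 0.20,
                                                      0.36),
                                       alpha = 0.5, p_inv = 0.2),
                                     host_clock = 0.15,
                                     parasite_clock = 0.3, seed = NULL) {
  if (is.null(seed)) stop("seed is mandatory for dataset simulation")
  seeds <- derive_seeds(seed, 4)
  host <- simulate_host_tree(n_hosts, birth_rate, seed = seeds[[1]])
  scen <- NULL
  for (try in 0:9) {  # losses may empty the scenario; retry with new seed
    scen <- tryCatch(
      simulate_cophylogeny(host, switch_rate, loss_rate,
                           seed = seeds[[2]] + try,
                           n_switches = n_switches, n_losses = n_losses),
      error = function(e) NULL)
    if (!is.null(scen)) break
  }
  if (is.null(scen)) stop("empty scenario after 10 attempts; lower loss_rate")
  bearing <- scen$parasite_tree$tip.label
  aln_h <- simulate_alignment(scen$host_tree, model, seq_length[1],
                              seed = seeds[[3]], rate_scale = host_clock)
  aln_p <- simulate_alignment(scen$parasite_tree, model, seq_length[2],
                              seed = seeds[[4]],
                              rate_scale = parasite_clock)
  structure(c(unclass(scen),
              list(aln_host = aln_h[bearing, , drop = FALSE],
                   aln_parasite = aln_p,
                   links = scen$association, seed = seed)),
            class = "cophylo_dataset")
}
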