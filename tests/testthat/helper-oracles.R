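# Independent brute-force oracles. These deliberately share no code with
# the package: serialization, matching and branch enumeration are written
# out longhand so agreement is a genuine cross-check.

oracle_serialize <- function(row) {
  paste0("d__", row$domain, ";p__", row$phylum, ";c__", row$class,
         ";o__", row$order, ";f__", row$family, ";g__", row$genus,
         ";s__", row$species)
}

oracle_match <- function(a, b, rank) {
  na <- a[[rank]]
  nb <- b[[rank]]
  nchar(na) > 0 && nchar(nb) > 0 && na == nb
}

# enumerate every (prediction, link) tuple per contig under each rank and
# mode; returns the same rank/mode/count grid as concordance_report
oracle_concordance <- function(pred, link) {
  ranks <- c("phylum", "class", "order", "family", "genus")
  modes <- c("strict", "top_vs_any", "any_vs_any")
  contigs <- intersect(unique(pred$contig_id), unique(link$contig_id))
  out <- expand.grid(rank = ranks, mode = modes, stringsAsFactors = FALSE)
  out$n_concordant <- 0L
  out$n_total <- length(contigs)
  for (ct in contigs) {
    p <- pred[pred$contig_id == ct, , drop = FALSE]
    ser <- vapply(seq_len(nrow(p)), function(i)
      oracle_serialize(p[i, ]), character(1))
    p <- p[order(-p$confidence, ser), , drop = FALSE]
    h <- link[link$contig_id == ct, , drop = FALSE]
    h <- h[order(h$link_rank), , drop = FALSE]
    for (k in seq_len(nrow(out))) {
      rank <- out$rank[k]
      conc <- switch(out$mode[k],
        strict = oracle_match(p[1, ], h[1, ], rank),
        top_vs_any = {
          hit <- FALSE
          for (j in seq_len(nrow(h))) {
            if (oracle_match(p[1, ], h[j, ], rank)) hit <- TRUE
          }
          hit
        },
        any_vs_any = {
          hit <- FALSE
          for (i in seq_len(nrow(p))) for (j in seq_len(nrow(h))) {
            if (oracle_match(p[i, ], h[j, ], rank)) hit <- TRUE
          }
          hit
        })
      if (conc) out$n_concordant[k] <- out$n_concordant[k] + 1L
    }
  }
  out$percent <- ifelse(out$n_total > 0,
                        100 * out$n_concordant / out$n_total, NA_real_)
  out
}

# random small concordance instance: arbitrary (possibly internally
# inconsistent) lineages, ties in confidence, contigs private to either
# table
random_concordance_instance <- function(max_contigs = 10, max_hosts = 4) {
  ranks <- c("domain", "phylum", "class", "order", "family", "genus",
             "species")
  rand_lineage <- function() {
    row <- as.data.frame(as.list(setNames(
      paste0(substr(ranks, 1, 1), sample(3, length(ranks),
                                         replace = TRUE)), ranks)),
      stringsAsFactors = FALSE)
    row$domain <- "Bacteria"
    for (r in ranks[-1]) if (runif(1) < 0.15) row[[r]] <- ""
    row
  }
  n <- sample(max_contigs, 1)
  pred <- list()
  link <- list()
  for (i in seq_len(n)) {
    ct <- paste0("c", i)
    if (runif(1) < 0.85) {                      # contig has predictions
      np <- sample(max_hosts, 1)
      for (k in seq_len(np)) {
        pred[[length(pred) + 1]] <- cbind(
          data.frame(contig_id = ct, stringsAsFactors = FALSE),
          rand_lineage(),
          confidence = sample(0:5, 1))          # small range forces ties
      }
    }
    if (runif(1) < 0.85) {                      # contig has Hi-C links
      nh <- sample(max_hosts, 1)
      for (k in seq_len(nh)) {
        link[[length(link) + 1]] <- cbind(
          data.frame(contig_id = ct, stringsAsFactors = FALSE),
          rand_lineage(), link_rank = k)
      }
    }
  }
  list(pred = if (length(pred)) do.call(rbind, pred) else NULL,
       link = if (length(link)) do.call(rbind, link) else NULL)
}

# exhaustive branch enumeration: walk down from every edge to its
# descendant tips, then apply the UniFrac definitions directly
oracle_unifrac <- function(tree, x, y, weighted) {
  ntip <- length(tree$tip.label)
  desc_tips <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc_tips))
  }
  num <- 0
  den <- 0
  for (e in seq_len(nrow(tree$edge))) {
    tips <- desc_tips(tree$edge[e, 2])
    L <- tree$edge.length[e]
    mx <- sum(x[names(x) %in% tips])
    my <- sum(y[names(y) %in% tips])
    if (weighted) {
      px <- mx / sum(x)
      py <- my / sum(y)
      num <- num + L * abs(px - py)
      den <- den + L * (px + py)
    } else {
      num <- num + L * xor(mx > 0, my > 0)
      den <- den + L * (mx > 0 || my > 0)
    }
  }
  num / den
}

# random rooted tree with <= max_tips tips, positive branch lengths, and
# a pair of random abundance vectors with some structural zeros
random_unifrac_case <- function(max_tips = 6) {
  n <- sample(2:max_tips, 1)
  tree <- ape::rtree(n, rooted = TRUE)
  tree$edge.length <- runif(length(tree$edge.length), 0.05, 2)
  repeat {
    x <- setNames(round(rlnorm(n, 0, 1), 3) * rbinom(n, 1, 0.7),
                  tree$tip.label)
    y <- setNames(round(rlnorm(n, 0, 1), 3) * rbinom(n, 1, 0.7),
                  tree$tip.label)
    if (sum(x) > 0 && sum(y) > 0) break
  }
  list(tree = tree, x = x, y = y)
}

# random abundance table with a random family grouping, for the
# aggregation-inequality property
random_grouped_table <- function(n_features = 30, n_samples = 6,
                                 n_families = 8) {
  m <- matrix(rlnorm(n_features * n_samples, 0, 1.5) *
                rbinom(n_features * n_samples, 1, 0.8),
              nrow = n_features,
              dimnames = list(paste0("f", seq_len(n_features)),
                              paste0("s", seq_len(n_samples))))
  zero <- colSums(m) == 0
  if (any(zero)) m[1, zero] <- 1        # keep compositions defined
  fam <- sample(paste0("Fam", seq_len(n_families)), n_features,
                replace = TRUE)
  assign <- data.frame(contig_id = rownames(m), phf = fam,
                       confidence = 90, stringsAsFactors = FALSE)
  class(assign) <- c("phf_assignment", "data.frame")
  list(table = phf_abundance(m), assign = assign)
}
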