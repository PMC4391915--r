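# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths wherever they check one.

# Residual sum of squares of a 4PL parameter set against data.
ss_4pl <- function(par, logd, fold) {
  pred <- par[["bottom"]] + (par[["emax"]] - par[["bottom"]]) /
    (1 + 10^(par[["hill"]] * (par[["logec50"]] - logd)))
  sum((fold - pred)^2)
}

# Exhaustive grid search over (logec50, hill, emax, bottom).
grid_search_4pl <- function(logd, fold, logec50_grid, hill_grid, emax_grid,
                            bottom_grid) {
  best <- NULL
  for (le in logec50_grid) for (h in hill_grid) {
    for (e in emax_grid) for (b in bottom_grid) {
      par <- c(logec50 = le, hill = h, emax = e, bottom = b)
      ss <- ss_4pl(par, logd, fold)
      if (is.null(best) || ss < best$ss) best <- list(par = par, ss = ss)
    }
  }
  best
}

# Brute-force global alignment by enumeration of every alignment path, with
# affine gaps costing (open + L * ext) per maximal gap run. Returns the
# optimal score and the set of gap-excluded identity values achieved by
# optimal alignments. Only viable for tiny sequences.
brute_align <- function(a, b, open = 10, ext = 0.5) {
  sm <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  results <- new.env()
  results$best <- -Inf
  results$idents <- numeric()
  rec <- function(i, j, score, last, match, cols) {
    if (i > length(av) && j > length(bv)) {
      if (score > results$best + 1e-9) {
        results$best <- score
        results$idents <- if (cols > 0) 100 * match / cols else numeric()
      } else if (abs(score - results$best) <= 1e-9) {
        results$idents <- unique(c(results$idents,
                                   if (cols > 0) 100 * match / cols))
      }
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv)) {
      rec(i + 1, j + 1, score + sm[av[i], bv[j]], "d",
          match + (av[i] == bv[j]), cols + 1)
    }
    if (i <= length(av)) {  # gap in b
      pen <- ext + if (last == "a") 0 else open
      rec(i + 1, j, score - pen, "a", match, cols)
    }
    if (j <= length(bv)) {  # gap in a
      pen <- ext + if (last == "b") 0 else open
      rec(i, j + 1, score - pen, "b", match, cols)
    }
  }
  rec(1, 1, 0, "none", 0, 0)
  list(score = results$best, identities = results$idents)
}

# Exact clade-recapitulation frequency over all ordered bootstrap samples of
# the assay rows of a small matrix (n^n ordered samples).
enum_bootstrap_freq <- function(am, target) {
  z <- zscore_rows(am$values)
  n <- nrow(z)
  idx_grid <- do.call(expand.grid, rep(list(seq_len(n)), n))
  hits <- 0
  for (r in seq_len(nrow(idx_grid))) {
    zb <- zscore_rows(z[as.integer(idx_grid[r, ]), , drop = FALSE])
    if (is_clade(cluster_species(zb), target)) hits <- hits + 1
  }
  hits / nrow(idx_grid)
}

# Clade sets of a merge matrix, for comparing tree topologies.
clade_strings <- function(merge, labels) {
  sets <- vector("list", nrow(merge))
  for (i in seq_len(nrow(merge))) {
    g <- function(k) if (k < 0) labels[-k] else sets[[k]]
    sets[[i]] <- sort(c(g(merge[i, 1]), g(merge[i, 2])))
  }
  vapply(sets, paste, character(1), collapse = "|")
}

# A small planted-structure assay matrix used by several tests: `n_driver`
# SRC1-flagged assays separate {A,B} from {C,D,E}; `n_null` unflagged assays
# carry noise only.
planted_matrix <- function(effect_size = 10, noise_sd = 1, n_driver = 5,
                           n_null = 5, seed = 42) {
  ids <- paste0("a", seq_len(n_driver + n_null))
  coreg <- c(rep(list("SRC1"), n_driver),
             rep(list(character()), n_null))
  names(coreg) <- ids
  spec <- matrix_sim_spec(
    species_labels = c("A", "B", "C", "D", "E"),
    assay_ids = ids,
    coregulator_groups = coreg,
    planted_partition = c(A = 1, B = 1, C = 2, D = 2, E = 2),
    effect_size = effect_size,
    driver_groups = "SRC1",
    noise_sd = noise_sd,
    seed = seed
  )
  simulate_assay_matrix(spec)
}
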