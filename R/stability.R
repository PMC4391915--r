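#' Bootstrap stability of species clusters
#'
#' For each of `n_boot` bootstrap replicates, assay rows are resampled with
#' replacement (keeping the row count), rows are re-standardized as
#' z-scores, species are re-clustered (Manhattan distance, complete
#' linkage), and each named target species set is checked for clade
#' recapitulation. The recapitulation frequency of a target is the fraction
#' of replicates in which it appears as the exact leaf set of an internal
#' node (`mode = "clade"`, default) or as one whole cluster when the
#' dendrogram is cut into `k` clusters (`mode = "kcut"`).
#'
#' The pairwise co-occurrence matrix records, for every species pair, the
#' fraction of replicates in which both fall in the same cluster at the
#' `k`-cluster cut (k = 3 by default, matching the three empirical
#' ortholog/paralog clusters this analysis is built around).
#'
#' @param x An [assay_matrix()] (raw or already standardized; rows are
#'   re-standardized internally after resampling).
#' @param targets Named list of character vectors of species labels.
#' @param n_boot Number of bootstrap replicates (>= 1; the study value is
#'   10,000).
#' @param seed Integer seed; results are reproducible given it.
#' @param mode `"clade"` (topology-based, cut-free) or `"kcut"`.
#' @param k Number of clusters for the k-cut mode and for co-occurrence.
#' @return An object of class `stability_report`: list with `targets`,
#'   `n_boot`, `recapitulation` (named frequencies in \[0, 1\]),
#'   `cooccurrence` (symmetric matrix, unit diagonal), `mode`, `k`, `seed`.
#' @examples
#' spec <- matrix_sim_spec(
#'   species_labels = c("A", "B", "C", "D"),
#'   assay_ids = paste0("a", 1:6),
#'   coregulator_groups = setNames(rep(list("SRC1"), 6), paste0("a", 1:6)),
#'   planted_partition = c(A = 1, B = 1, C = 2, D = 2),
#'   effect_size = 8, driver_groups = "SRC1", noise_sd = 1, seed = 2)
#' rep <- bootstrap_stability(simulate_assay_matrix(spec),
#'                            targets = list(AB = c("A", "B")),
#'                            n_boot = 200, seed = 1)
#' rep$recapitulation
#' @export
bootstrap_stability <- function(x, targets, n_boot = 10000L, seed = 1L,
                                mode = c("clade", "kcut"), k = 3L) {
  mode <- match.arg(mode)
  if (!inherits(x, "assay_matrix")) {
    stop("'x' must be an assay_matrix", call. = FALSE)
  }
  if (n_boot < 1 || n_boot != round(n_boot)) {
    stop("'n_boot' must be a positive integer", call. = FALSE)
  }
  targets <- check_targets(targets, x$species)
  vals <- zscore_rows(x$values)
  n_assay <- nrow(vals)
  n_sp <- ncol(vals)
  hits <- setNames(numeric(length(targets)), names(targets))
  co <- matrix(0, n_sp, n_sp, dimnames = list(x$species, x$species))
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n_assay, n_assay, replace = TRUE)
      zb <- zscore_rows(vals[idx, , drop = FALSE])
      tree <- cluster_species(zb)
      for (t in seq_along(targets)) {
        if (target_recapitulated(tree, targets[[t]], mode, k)) {
          hits[t] <- hits[t] + 1
        }
      }
      memb <- cut_tree(tree, k = min(k, n_sp))
      co <- co + outer(memb[x$species], memb[x$species], "==")
    }
  })
  structure(list(targets = targets, n_boot = as.integer(n_boot),
                 recapitulation = hits / n_boot,
                 cooccurrence = co / n_boot,
                 mode = mode, k = as.integer(k), seed = as.integer(seed)),
            class = "stability_report")
}

check_targets <- function(targets, species) {
  if (!is.list(targets) || is.null(names(targets)) ||
      any(!nzchar(names(targets)))) {
    stop("'targets' must be a named list of species sets", call. = FALSE)
  }
  for (nm in names(targets)) {
    unknown <- setdiff(targets[[nm]], species)
    if (length(unknown)) {
      stop(sprintf("target '%s' contains unknown species: %s", nm,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
  }
  lapply(targets, as.character)
}

target_recapitulated <- function(tree, target, mode, k) {
  if (mode == "clade") return(is_clade(tree, target))
  memb <- cut_tree(tree, k = min(k, length(tree$labels)))
  in_t <- memb[target]
  length(unique(in_t)) == 1 &&
    sum(memb == in_t[1]) == length(unique(target))
}

#' @export
print.stability_report <- function(x, digits = 3, ...) {
  cat(sprintf("Bootstrap cluster stability (%d replicates, %s mode)\n",
              x$n_boot, x$mode))
  for (nm in names(x$recapitulation)) {
    cat(sprintf("  %s {%s}: %.*f\n", nm,
                paste(x$targets[[nm]], collapse = ", "), digits,
                x$recapitulation[[nm]]))
  }
  invisible(x)
}

#' Driver-coregulator inference by within-row permutation
#'
#' Identifies assays (or coregulator-defined assay groups) that drive a
#' species cluster: for each permutation replicate the species values within
#' every selected assay row are shuffled independently — destroying that
#' row's species signal while preserving its marginal distribution — the
#' matrix is re-standardized and re-clustered, and clade recapitulation of
#' each target is recorded. A large drop from the baseline (bootstrap)
#' frequency marks the selected assays as drivers of that cluster.
#'
#' @param x An [assay_matrix()].
#' @param targets Named list of species sets (as in [bootstrap_stability()]).
#' @param grouping Either coregulator label(s) (rows whose annotation
#'   contains any of them are selected) or assay ids.
#' @param n_perm Number of permutation replicates.
#' @param seed Integer seed.
#' @param n_boot Bootstrap replicates for the baseline frequencies.
#' @param mode,k Recapitulation mode, as in [bootstrap_stability()].
#' @return An object of class `driver_report`: data frame `table` with one
#'   row per target (`target`, `baseline_freq`, `permuted_freq`, `delta`),
#'   plus the selected assay ids and settings.
#' @export
driver_analysis <- function(x, targets, grouping, n_perm = 10000L,
                            seed = 1L, n_boot = n_perm,
                            mode = c("clade", "kcut"), k = 3L) {
  mode <- match.arg(mode)
  if (!inherits(x, "assay_matrix")) {
    stop("'x' must be an assay_matrix", call. = FALSE)
  }
  targets <- check_targets(targets, x$species)
  sel_by_coreg <- vapply(x$coregulators,
                         function(g) length(intersect(g, grouping)) > 0,
                         logical(1))
  sel <- if (any(sel_by_coreg)) which(sel_by_coreg)
         else which(x$assay_ids %in% grouping)
  if (!length(sel)) {
    stop("'grouping' selects no assay rows", call. = FALSE)
  }
  vals <- zscore_rows(x$values)
  n_sp <- ncol(vals)
  base <- bootstrap_stability(x, targets, n_boot = n_boot, seed = seed,
                              mode = mode, k = k)
  hits <- setNames(numeric(length(targets)), names(targets))
  with_seed(seed + 1L, {
    for (p in seq_len(n_perm)) {
      vp <- vals
      for (r in sel) vp[r, ] <- vp[r, sample.int(n_sp)]
      tree <- cluster_species(zscore_rows(vp))
      for (t in seq_along(targets)) {
        if (target_recapitulated(tree, targets[[t]], mode, k)) {
          hits[t] <- hits[t] + 1
        }
      }
    }
  })
  tab <- data.frame(target = names(targets),
                    baseline_freq = unname(base$recapitulation),
                    permuted_freq = unname(hits / n_perm),
                    stringsAsFactors = FALSE, row.names = NULL)
  tab$delta <- tab$permuted_freq - tab$baseline_freq
  structure(list(table = tab, assays_permuted = x$assay_ids[sel],
                 grouping = grouping, n_perm = as.integer(n_perm),
                 n_boot = as.integer(n_boot), mode = mode,
                 k = as.integer(k), seed = as.integer(seed)),
            class = "driver_report")
}

#' @export
print.driver_report <- function(x, digits = 3, ...) {
  cat(sprintf("Driver analysis: permuted %d assay row(s) [%s], %d replicates\n",
              length(x$assays_permuted),
              paste(x$grouping, collapse = ", "), x$n_perm))
  print(x$table, digits = digits)
  invisible(x)
}

#' Write a stability or driver report as JSON
#'
#' @param report A `stability_report` or `driver_report`.
#' @param file Path to write.
#' @return The path, invisibly.
#' @export
write_report_json <- function(report, file) {
  x <- unclass(report)
  if (!is.null(x$recapitulation)) x$recapitulation <- as.list(x$recapitulation)
  if (!is.null(x$cooccurrence)) {
    x$cooccurrence <- list(species = rownames(x$cooccurrence),
                           matrix = unname(x$cooccurrence))
  }
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
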