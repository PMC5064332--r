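# End-to-end two-group twin analysis: read/validate pair records, balance the
# zygosity groups, estimate per-group polychoric correlations, fit the
# variance-component models, run the nested comparisons and Falconer
# heritability, and optionally repeat with the most severe category removed.

#' Read twin-pair records from CSV
#'
#' Expects columns `pair_id`, `zygosity`, `score1`, `score2`. Rows with an
#' unknown zygosity token or a score outside `0:(K-1)` are rejected with a
#' row-numbered warning; duplicated pair ids are an error.
#'
#' @param path CSV path.
#' @param K Number of ordinal categories (default 4).
#' @return Data frame of validated records with attribute `n_rejected`.
#' @export
read_twin_pairs <- function(path, K = 4) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("pair_id", "zygosity", "score1", "score2")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0) stop("empty twin-pair file: ", path)
  df$zygosity <- toupper(trimws(df$zygosity))
  ok_zyg <- df$zygosity %in% c("MZ", "DZ")
  s1 <- suppressWarnings(as.integer(df$score1))
  s2 <- suppressWarnings(as.integer(df$score2))
  ok_score <- !is.na(s1) & !is.na(s2) &
    s1 >= 0 & s1 < K & s2 >= 0 & s2 < K
  bad <- which(!(ok_zyg & ok_score))
  if (length(bad)) {
    warning("rejected ", length(bad), " invalid row(s): ",
            paste(utils::head(bad, 10), collapse = ", "),
            if (length(bad) > 10) " ...")
    df <- df[-bad, , drop = FALSE]
    s1 <- s1[-bad]
    s2 <- s2[-bad]
  }
  if (nrow(df) == 0) stop("no valid twin-pair rows in ", path)
  dup <- df$pair_id[duplicated(df$pair_id)]
  if (length(dup))
    stop("duplicated pair_id(s): ", paste(unique(dup), collapse = ", "))
  out <- data.frame(pair_id = df$pair_id, zygosity = df$zygosity,
                    score1 = s1, score2 = s2, stringsAsFactors = FALSE)
  attr(out, "n_rejected") <- length(bad)
  out
}

#' Write twin-pair records to CSV
#'
#' @param pairs Data frame of twin-pair records.
#' @param path Output CSV path.
#' @export
write_twin_pairs <- function(pairs, path) {
  write.csv(pairs[, c("pair_id", "zygosity", "score1", "score2")], path,
            row.names = FALSE)
  invisible(path)
}

#' Randomly equalize the MZ and DZ group sizes
#'
#' Downsamples the larger zygosity group, without replacement, to the size of
#' the smaller one (as done before a two-group analysis so that both groups
#' carry equal weight).
#'
#' @param pairs Data frame of twin-pair records.
#' @param seed Optional integer seed for a deterministic selection.
#' @return Data frame with equal MZ and DZ pair counts; attribute
#'   `n_dropped` records how many pairs were removed.
#' @export
balanced_subsample <- function(pairs, seed = NULL) {
  n_mz <- sum(pairs$zygosity == "MZ")
  n_dz <- sum(pairs$zygosity == "DZ")
  if (n_mz == 0 || n_dz == 0)
    stop("both zygosity groups must be non-empty (MZ: ", n_mz, ", DZ: ", n_dz, ")")
  if (!is.null(seed)) set.seed(seed)
  n_keep <- min(n_mz, n_dz)
  larger <- if (n_mz > n_dz) "MZ" else "DZ"
  idx_larger <- which(pairs$zygosity == larger)
  keep <- sort(c(which(pairs$zygosity != larger),
                 sample(idx_larger, n_keep)))
  out <- pairs[keep, , drop = FALSE]
  attr(out, "n_dropped") <- nrow(pairs) - length(keep)
  out
}

# Analysis of one arm (full or severity-restricted): correlations, model
# fits, nested tests, Falconer heritability, and a parsimony-guided model
# selection starting from the saturated ADE model.
.analyze_arm <- function(pairs, K, alpha, models) {
  est <- polychoric_by_zygosity(pairs, K)
  fits_tab <- fit_all_models(est$corr, models)
  fits <- attr(fits_tab, "fits")
  names(fits) <- models
  nested <- list()
  if ("ADE" %in% models) {
    for (red in intersect(c("AE", "DE", "E"), models))
      nested[[paste0("ADE_vs_", red)]] <- compare_nested(fits[["ADE"]], fits[[red]])
  }
  if (all(c("ACE", "AE") %in% models))
    nested[["ACE_vs_AE"]] <- compare_nested(fits[["ACE"]], fits[["AE"]])
  # parsimony rule: keep the most parsimonious model nested in ADE whose
  # chi-square difference test against ADE is non-significant at alpha
  best <- if ("ADE" %in% models) "ADE" else models[1]
  justification <- "saturated ADE retained"
  for (red in intersect(c("E", "DE", "AE"), models)) {   # most parsimonious first
    nt <- nested[[paste0("ADE_vs_", red)]]
    if (!is.null(nt) && nt$p >= alpha) {
      best <- red
      justification <- sprintf("%s not rejected against ADE (delta chi2 = %.2f, df = %d, p = %.2f)",
                               red, nt$delta_chi2, nt$df, nt$p)
      break
    }
  }
  list(
    n_mz = est$mz$n_pairs, n_dz = est$dz$n_pairs, K = K,
    polychoric = list(mz = est$mz, dz = est$dz),
    corr = est$corr,
    falconer = falconer_heritability(est$corr$r_mz, est$corr$r_dz),
    fits = fits_tab,
    nested = nested,
    best_model = best,
    best_justification = justification
  )
}

#' Run the full two-group twin analysis
#'
#' Pipeline: (optionally) balance the MZ/DZ group sizes by random
#' subsampling, double-enter each group, estimate polychoric correlations,
#' fit the variance-component models, run the nested chi-square comparisons
#' and Falconer heritability, and (optionally) repeat with the most severe
#' category removed — either dropping every pair in which at least one twin
#' scores `K-1` (default, mirroring a reduced pair count) or recoding those
#' scores down one level.
#'
#' @param pairs Data frame of twin-pair records (`pair_id`, `zygosity`,
#'   `score1`, `score2`).
#' @param K Number of ordinal categories (default 4).
#' @param seed Optional seed for the balancing subsample.
#' @param balance Equalize group sizes before analysis (default TRUE).
#' @param severity_restricted Also run the arm with the top category removed
#'   (default TRUE when `K > 2`).
#' @param restricted_mode `"drop"` (remove pairs containing a top-category
#'   score) or `"recode"` (merge the top category into the one below).
#' @param alpha Significance level for nested-model selection (default 0.05).
#' @param models Models to fit.
#' @param min_pairs Minimum pairs per zygosity group (default 30).
#' @return Object of class `"twin_analysis"`: a counts ledger, the full-arm
#'   results, and (optionally) the severity-restricted arm.
#' @examples
#' pairs <- simulate_twin_pairs(twin_components(a2 = 0.27, d2 = 0.25),
#'                              n_mz = 1000, n_dz = 800, seed = 11)
#' run_full_analysis(pairs, seed = 1)
#' @export
run_full_analysis <- function(pairs, K = 4, seed = NULL, balance = TRUE,
                              severity_restricted = K > 2,
                              restricted_mode = c("drop", "recode"),
                              alpha = 0.05,
                              models = c("ADE", "ACE", "AE", "CE", "DE", "E"),
                              min_pairs = 30) {
  restricted_mode <- match.arg(restricted_mode)
  counts <- list(n_input = nrow(pairs))
  if (balance) {
    pairs <- balanced_subsample(pairs, seed = seed)
    counts$n_subsampled_out <- attr(pairs, "n_dropped")
  } else {
    counts$n_subsampled_out <- 0L
  }
  counts$n_analyzed <- nrow(pairs)
  for (z in c("MZ", "DZ")) {
    nz <- sum(pairs$zygosity == z)
    if (nz < min_pairs)
      stop("stage group-check: only ", nz, " ", z, " pairs (< ", min_pairs, ")")
  }
  full <- .analyze_arm(pairs, K, alpha, models)
  restricted <- NULL
  if (severity_restricted) {
    top <- K - 1L
    if (restricted_mode == "drop") {
      keep <- pairs$score1 < top & pairs$score2 < top
      rp <- pairs[keep, , drop = FALSE]
      counts$n_restricted_dropped <- sum(!keep)
    } else {
      rp <- pairs
      rp$score1 <- pmin(rp$score1, top - 1L)
      rp$score2 <- pmin(rp$score2, top - 1L)
      counts$n_restricted_dropped <- 0L
    }
    counts$n_restricted <- nrow(rp)
    enough <- all(vapply(c("MZ", "DZ"),
                         function(z) sum(rp$zygosity == z) >= min_pairs, logical(1)))
    if (enough) {
      restricted <- .analyze_arm(rp, K - 1L, alpha, models)
      restricted$mode <- restricted_mode
    } else {
      warning("severity-restricted arm skipped: fewer than ", min_pairs,
              " pairs in a zygosity group after restriction")
    }
  }
  structure(list(counts = counts, full = full, restricted = restricted,
                 config = list(K = K, seed = seed, balance = balance,
                               restricted_mode = restricted_mode,
                               alpha = alpha, models = models,
                               min_pairs = min_pairs)),
            class = "twin_analysis")
}

.print_arm <- function(arm, label) {
  cat("\n== ", label, " (", arm$n_mz, " MZ + ", arm$n_dz, " DZ pairs, K = ",
      arm$K, ") ==\n", sep = "")
  cat(sprintf("  r_MZ = %.3f (se %.3f), r_DZ = %.3f (se %.3f)\n",
              arm$corr$r_mz, arm$corr$se_mz, arm$corr$r_dz, arm$corr$se_dz))
  cat(sprintf("  Falconer broad-sense heritability: %.2f\n", arm$falconer))
  cat("  Model fits (df = 2 - free parameters off boundary):\n")
  tab <- arm$fits
  tab[c("a2", "c2", "d2", "e2", "chi2")] <- round(tab[c("a2", "c2", "d2", "e2", "chi2")], 3)
  tab$p <- round(tab$p, 2)
  print(tab, row.names = FALSE)
  for (nt in arm$nested)
    cat(sprintf("  %s vs %s: delta chi2 = %.2f, df = %d, p = %.2f\n",
                nt$reduced, nt$full, nt$delta_chi2, nt$df, nt$p))
  cat("  Selected model: ", arm$best_model, " (", arm$best_justification, ")\n", sep = "")
}

#' @export
print.twin_analysis <- function(x, ...) {
  cat("Two-group liability-threshold twin analysis\n")
  cat("Counts: input =", x$counts$n_input,
      "| subsampled out =", x$counts$n_subsampled_out,
      "| analyzed =", x$counts$n_analyzed, "\n")
  .print_arm(x$full, "All severity levels")
  if (!is.null(x$restricted)) {
    cat("\nSeverity-restricted arm: ", x$counts$n_restricted_dropped,
        " pair(s) removed (mode: ", x$restricted$mode, ")\n", sep = "")
    .print_arm(x$restricted, "Top severity level excluded")
  }
  invisible(x)
}
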