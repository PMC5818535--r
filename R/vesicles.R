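#' Classify vesicles into singles, pairs, and larger clusters
#'
#' Builds a graph with an edge between every two vesicles whose
#' center-to-center distance is at most `radius` (default 250 nm) and takes
#' connected components as clusters: linkage is transitive, so a chain A-B-C
#' is one cluster of three even when A and C are far apart. Percentages are
#' reported over vesicles by default (a pair contributes two vesicles to the
#' pair category); `denominator = "components"` reports percentages of
#' clusters instead. Exact duplicate coordinates (within 1 nm) are merged with
#' a warning.
#'
#' @param spots data frame with columns `x_nm`, `y_nm`; at least one row.
#' @param radius linkage radius in nm (default 250).
#' @param denominator `"vesicles"` (default) or `"components"`.
#' @return data frame with `pct_singles`, `pct_pairs`, `pct_multi` (component
#'   size >= 3), `n_vesicles`, `n_components`; percentages sum to 100.
#' @export
classify_clusters <- function(spots, radius = 250,
                              denominator = c("vesicles", "components")) {
  denominator <- match.arg(denominator)
  if (nrow(spots) == 0) stop("empty spot table")
  xy <- as.matrix(spots[, c("x_nm", "y_nm")])
  if (nrow(xy) > 1) {
    comp0 <- stats::cutree(stats::hclust(stats::dist(xy), method = "single"),
                           h = 1)
    if (max(comp0) < nrow(xy)) {
      warning(sprintf("merged %d duplicate coordinate(s) within 1 nm",
                      nrow(xy) - max(comp0)))
      xy <- do.call(rbind, lapply(split(seq_len(nrow(xy)), comp0),
                                  function(i) colMeans(xy[i, , drop = FALSE])))
    }
  }
  n <- nrow(xy)
  comp <- if (n == 1) 1L else {
    stats::cutree(stats::hclust(stats::dist(xy), method = "single"), h = radius)
  }
  sizes <- as.integer(table(comp))
  cat_of <- cut(sizes, c(0, 1, 2, Inf), labels = c("single", "pair", "multi"))
  weight <- if (denominator == "vesicles") sizes else rep(1L, length(sizes))
  tot <- sum(weight)
  pct <- vapply(c("single", "pair", "multi"),
                function(k) 100 * sum(weight[cat_of == k]) / tot, numeric(1))
  data.frame(pct_singles = pct[["single"]], pct_pairs = pct[["pair"]],
             pct_multi = pct[["multi"]], n_vesicles = n,
             n_components = length(sizes))
}

#' Compare vesicle cluster-size distributions across conditions
#'
#' Per size category (singles, pairs, multi), a one-way ANOVA over conditions
#' followed by Tukey-adjusted pairwise comparisons of the per-field
#' percentages. Degenerate categories (zero variance everywhere) are flagged
#' rather than tested.
#'
#' @param dists named list: condition -> data frame of per-field
#'   classifications rbind-ed from [classify_clusters()] (>= 2 replicates
#'   each).
#' @return list with `anova` (per category F and p) and `pairwise` (Tukey
#'   table per category with adjusted p-values).
#' @export
compare_conditions <- function(dists) {
  if (length(dists) < 2) stop("need at least 2 conditions")
  for (nm in names(dists)) {
    if (nrow(dists[[nm]]) < 2) {
      stop(sprintf("condition '%s' has a single replicate; need >= 2", nm))
    }
  }
  long <- do.call(rbind, lapply(names(dists), function(nm) {
    cbind(condition = nm, dists[[nm]])
  }))
  long$condition <- factor(long$condition)
  cats <- c(singles = "pct_singles", pairs = "pct_pairs", multi = "pct_multi")
  anova_rows <- list()
  pairwise <- list()
  for (k in names(cats)) {
    y <- long[[cats[[k]]]]
    if (stats::sd(y) == 0) {
      anova_rows[[k]] <- data.frame(category = k, F = NA_real_, p = NA_real_,
                                    degenerate = TRUE)
      pairwise[[k]] <- NULL
      next
    }
    fit <- stats::aov(y ~ condition, data = long)
    an <- summary(fit)[[1]]
    anova_rows[[k]] <- data.frame(category = k, F = an[1, "F value"],
                                  p = an[1, "Pr(>F)"], degenerate = FALSE)
    tk <- stats::TukeyHSD(fit)$condition
    pairwise[[k]] <- data.frame(comparison = rownames(tk), tk,
                                row.names = NULL, check.names = FALSE)
  }
  list(anova = do.call(rbind, c(anova_rows, make.row.names = FALSE)),
       pairwise = pairwise)
}
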