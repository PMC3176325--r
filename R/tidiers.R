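#' Tidy a cluster permutation result
#'
#' @param x a `cluster_result`.
#' @param ... unused.
#' @return tibble with one row per cluster: cluster, polarity, mass,
#'   n_points, n_channels, time range (sample indices), p, significant.
#' @exportS3Method generics::tidy
tidy.cluster_result <- function(x, ...) {
  cl <- x$clusters
  if (!nrow(cl)) {
    return(tibble::tibble(cluster = integer(), polarity = character(),
                          mass = numeric(), n_points = integer(),
                          n_channels = integer(), time_min = integer(),
                          time_max = integer(), p = numeric(),
                          significant = logical()))
  }
  tibble::tibble(
    cluster = cl$cluster, polarity = cl$polarity, mass = cl$mass,
    n_points = cl$n_points,
    n_channels = vapply(cl$members,
                        function(m) length(unique(m$channel)), integer(1)),
    time_min = vapply(cl$members, function(m) min(m$time_index), integer(1)),
    time_max = vapply(cl$members, function(m) max(m$time_index), integer(1)),
    p = cl$p, significant = cl$significant
  )
}

#' @rdname tidy.cluster_result
#' @exportS3Method generics::glance
glance.cluster_result <- function(x, ...) {
  tibble::tibble(
    n_clusters = nrow(x$clusters),
    n_significant = sum(x$clusters$significant),
    t_threshold = x$t_threshold,
    n_perm = x$n_perm,
    exact = x$exact,
    alpha = x$alpha
  )
}

#' Tidy an ERP ANOVA table
#'
#' @param x an `erp_anova`.
#' @param ... unused.
#' @return the underlying tibble (one row per component x measure x
#'   term).
#' @exportS3Method generics::tidy
tidy.erp_anova <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.erp_anova
#' @exportS3Method generics::glance
glance.erp_anova <- function(x, ...) {
  tibble::tibble(
    n_tests = nrow(x),
    df1 = unique(x$df1),
    df2 = unique(x$df2),
    n_significant_05 = sum(x$p < 0.05),
    estimator = unique(x$estimator)
  )
}
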