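#' Specification of a synthetic federated tabular benchmark
#'
#' Describes a Gaussian-mixture tabular classification population with
#' categorical attributes that shift the feature distribution, standing in
#' for clinical tables (risk-prediction extracts with demographic columns).
#' Class-conditional means sit on a regular simplex scaled so every pairwise
#' distance equals `class_separation`; each attribute value adds a fixed
#' displacement of length `attribute_shift` along a unit direction drawn once
#' per seed, so some attribute groups are genuinely harder and plain training
#' produces non-trivial disparity.
#'
#' @param n number of rows.
#' @param d feature dimension (must be >= K-1 when `class_separation > 0`).
#' @param K number of classes (>= 2).
#' @param n_clients number of simulated clients.
#' @param alpha Dirichlet heterogeneity of the client partition.
#' @param attribute_spec list of attribute descriptors, each a list with
#'   `name`, `n_values`, and `probs` (mixing proportions summing to 1).
#' @param class_separation pairwise distance between class-conditional means.
#' @param attribute_shift length of the per-attribute-value mean displacement.
#' @param label_noise probability a label is flipped to a different class.
#' @param seed integer master seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n = 2000L, d = 20L, K = 2L, n_clients = 4L,
                           alpha = 0.1,
                           attribute_spec = list(
                             list(name = "sex", n_values = 2L,
                                  probs = c(0.5, 0.5))),
                           class_separation = 2,
                           attribute_shift = 1,
                           label_noise = 0.05,
                           seed = 1L) {
  stopifnot(n >= 1, d >= 1, K >= 2, n_clients >= 1, alpha > 0,
            class_separation >= 0, attribute_shift >= 0,
            label_noise >= 0, label_noise < 1)
  if (class_separation > 0 && d < K - 1) {
    stop("d must be >= K-1 to place ", K,
         " class means at separation ", class_separation)
  }
  for (a in attribute_spec) {
    if (!all(c("name", "n_values", "probs") %in% names(a))) {
      stop("each attribute needs name, n_values, probs")
    }
    if (length(a$probs) != a$n_values) stop("probs length must equal n_values")
    if (abs(sum(a$probs) - 1) > 1e-8) stop("mixing proportions must sum to 1")
    if (any(a$probs < 0)) stop("mixing proportions must be nonnegative")
  }
  structure(
    list(n = as.integer(n), d = as.integer(d), K = as.integer(K),
         n_clients = as.integer(n_clients), alpha = as.numeric(alpha),
         attribute_spec = unname(lapply(attribute_spec, function(a) {
           list(name = a$name, n_values = as.integer(a$n_values),
                probs = as.numeric(a$probs))
         })),
         class_separation = as.numeric(class_separation),
         attribute_shift = as.numeric(attribute_shift),
         label_noise = as.numeric(label_noise), seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# K points in R^d with all pairwise distances == sep: scaled unit vectors,
# centered, rotated into their (K-1)-dimensional span, zero-padded to d.
class_means <- function(K, d, sep) {
  if (sep == 0) return(matrix(0, K, d))
  V <- diag(K) * sep / sqrt(2)
  V <- sweep(V, 2, colMeans(V))
  sv <- svd(V, nu = K, nv = 0)
  coords <- sv$u %*% diag(sv$d, K, K)      # K x K, last column ~ 0
  M <- matrix(0, K, d)
  r <- min(K - 1, d)
  M[, seq_len(r)] <- coords[, seq_len(r)]
  M
}

#' Draw a synthetic population
#'
#' Rows are i.i.d.: attribute values from their mixing proportions, a label
#' from the uniform class prior, features = class mean + sum of attribute
#' displacements + standard Gaussian noise; finally the label is flipped to a
#' uniformly chosen other class with probability `label_noise`. Deterministic
#' given `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return A [tabular_dataset()] carrying the generating spec in
#'   `attr(, "synthetic_spec")`.
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(substream_seed(spec$seed, "population"), {
    mu <- class_means(spec$K, spec$d, spec$class_separation)
    # one fixed unit displacement direction per attribute value
    shifts <- lapply(spec$attribute_spec, function(a) {
      U <- matrix(stats::rnorm(a$n_values * spec$d), a$n_values, spec$d)
      U / sqrt(rowSums(U^2)) * spec$attribute_shift
    })
    y <- sample.int(spec$K, spec$n, replace = TRUE) - 1L
    attrs <- lapply(spec$attribute_spec, function(a) {
      sample.int(a$n_values, spec$n, replace = TRUE, prob = a$probs) - 1L
    })
    names(attrs) <- vapply(spec$attribute_spec, `[[`, "", "name")
    X <- mu[y + 1L, , drop = FALSE]
    for (j in seq_along(attrs)) {
      X <- X + shifts[[j]][attrs[[j]] + 1L, , drop = FALSE]
    }
    X <- X + matrix(stats::rnorm(spec$n * spec$d), spec$n, spec$d)
    if (spec$label_noise > 0) {
      flip <- stats::runif(spec$n) < spec$label_noise
      if (any(flip)) {
        # uniform over the K-1 other classes
        y[flip] <- (y[flip] + sample.int(spec$K - 1L, sum(flip),
                                         replace = TRUE)) %% spec$K
      }
    }
    ds <- tabular_dataset(X, y, attrs)
    attr(ds, "synthetic_spec") <- spec
    ds
  })
}

#' Build a complete federated benchmark from a synthetic spec
#'
#' One call produces everything a training run consumes: the population, its
#' Dirichlet client partition, the per-client stratified train/test split,
#' and groupings for all four fairness levels (attribute groupings use the
#' first attribute column unless `attribute_columns` is given). A manifest
#' records every parameter and seed so the benchmark regenerates exactly.
#'
#' @param spec a [synthetic_spec()].
#' @param test_fraction per-client held-out fraction (default 0.2).
#' @param attribute_columns attribute columns used for the attribute-level,
#'   multilevel and agnostic groupings; default the first attribute.
#' @return list of class `fedufo_benchmark`: `dataset`, `partition`, `train`,
#'   `test`, `groupings` (named by level, built on the train view),
#'   `attribute_columns`, `manifest`.
#' @export
make_benchmark <- function(spec, test_fraction = 0.2,
                           attribute_columns = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dataset <- generate_population(spec)
  if (is.null(attribute_columns)) {
    attribute_columns <- names(dataset$attributes)[1]
  }
  partition <- partition_dirichlet(dataset, spec$n_clients, spec$alpha,
                                   seed = spec$seed)
  split <- split_train_test(partition, dataset, test_fraction,
                            seed = spec$seed)
  groupings <- list(
    client = build_grouping(dataset, split$train, "client"),
    attribute = build_grouping(dataset, split$train, "attribute",
                               attribute_columns),
    multilevel = build_grouping(dataset, split$train, "multilevel",
                                attribute_columns),
    agnostic = build_grouping(dataset, split$train, "agnostic",
                              attribute_columns)
  )
  manifest <- list(
    generator = "fedufo synthetic benchmark",
    spec = unclass(spec),
    test_fraction = test_fraction,
    attribute_columns = attribute_columns
  )
  structure(
    list(dataset = dataset, partition = partition,
         train = split$train, test = split$test,
         groupings = groupings, attribute_columns = attribute_columns,
         manifest = manifest),
    class = "fedufo_benchmark"
  )
}

#' Rebuild a benchmark from its manifest
#'
#' @param manifest a manifest list as stored in a benchmark, or a path to a
#'   manifest JSON file.
#' @return the regenerated `fedufo_benchmark`.
#' @export
benchmark_from_manifest <- function(manifest) {
  if (is.character(manifest)) {
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  }
  sp <- manifest$spec
  spec <- synthetic_spec(
    n = sp$n, d = sp$d, K = sp$K, n_clients = sp$n_clients, alpha = sp$alpha,
    attribute_spec = lapply(
      if (is.data.frame(sp$attribute_spec)) {
        split(sp$attribute_spec, seq_len(nrow(sp$attribute_spec)))
      } else sp$attribute_spec,
      function(a) list(name = as.character(a$name),
                       n_values = as.integer(a$n_values),
                       probs = as.numeric(unlist(a$probs)))),
    class_separation = sp$class_separation,
    attribute_shift = sp$attribute_shift,
    label_noise = sp$label_noise, seed = sp$seed
  )
  make_benchmark(spec, test_fraction = manifest$test_fraction,
                 attribute_columns = manifest$attribute_columns)
}

#' Write a benchmark to disk as plain-text artifacts
#'
#' Writes the data table as CSV, the partition as JSON and the manifest as
#' JSON into `dir`.
#'
#' @param benchmark a [make_benchmark()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(benchmark, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ds <- benchmark$dataset
  df <- as.data.frame(ds$features)
  df$label <- ds$labels
  for (nm in names(ds$attributes)) df[[nm]] <- ds$attributes[[nm]]
  utils::write.csv(df, file.path(dir, "data.csv"), row.names = FALSE)
  write_partition_json(benchmark$partition,
                       benchmark$groupings$client,
                       file.path(dir, "partition.json"))
  jsonlite::write_json(benchmark$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
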