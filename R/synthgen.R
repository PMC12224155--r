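#' Eluent (mobile-phase) descriptor columns
#'
#' The five mobile-phase properties appended to every instance: pH, presence
#' of ammonium (binary), polarity, viscosity and surface tension. These
#' columns are protected from descriptor cleaning.
#'
#' @return Character vector of the five eluent column names.
#' @export
eluent_columns <- function() {
  c("pH", "nh4", "polarity", "viscosity", "surface_tension")
}

#' Specification of a synthetic chemical space
#'
#' Describes a two-part chemical space: an *explored* space of chemicals
#' measured under several eluent conditions (the training set of a log IE
#' model) and an *unexplored* space of candidate chemicals split into
#' chemically distinct classes whose descriptor distributions are offset
#' from the explored region. The response is log IE on a log10 scale.
#'
#' Defaults mirror a realistic ionization-efficiency campaign: 81 explored
#' chemicals measured under 8-17 mobile-phase conditions each (~1000
#' instances), 369 unexplored chemicals in 4 classes of unequal size
#' (proportions 0.35/0.30/0.20/0.15), and a linear descriptor response with
#' measurement noise of 0.3 log IE units.
#'
#' @param n_explored_chemicals Number of chemicals in the explored space.
#' @param n_unexplored_chemicals Number of chemicals in the unexplored pool.
#' @param n_classes Number of unexplored chemical classes.
#' @param class_proportions Relative class sizes (normalized internally).
#' @param n_descriptors Number of molecular descriptor columns
#'   (`d0001`...). Must be at least `n_informative + 4`: the generator
#'   reserves two highly collinear copies of informative descriptors and
#'   two near-constant columns so the cleaning filters have work to do.
#' @param n_informative Number of descriptors that drive the response.
#' @param n_conditions_per_chemical Integer range (length 2) of eluent
#'   conditions per explored chemical; each unexplored chemical is measured
#'   once under the reference condition.
#' @param class_shift Distance of each unexplored class center from the
#'   explored center, in units of `cluster_spread`. Larger values reduce
#'   explored/unexplored overlap.
#' @param cluster_spread Within-class descriptor standard deviation.
#' @param noise_sd Response noise standard deviation (log IE units).
#' @param condition_effect Length-5 coefficient vector for the (scaled)
#'   eluent descriptors, in [eluent_columns()] order.
#' @param class_offset_sd Standard deviation of the per-class response
#'   offsets (log IE units).
#' @param nonlinear If `TRUE`, the response adds pairwise products of the
#'   first informative descriptors, giving tree ensembles an edge over a
#'   linear fit.
#' @param price_model Parameters for [generate_prices()]: `meanlog`,
#'   `sdlog` of a lognormal base price, `density_coupling` (slope of log
#'   price on the standardized d_NN=5 distance to the rest of the pool;
#'   positive makes sparse-region chemicals expensive) and
#'   `unavailable_frac` (fraction of chemicals without a vendor price).
#' @param seed Integer seed; identical spec + seed gives identical output.
#'
#' @return An object of class `space_spec`.
#' @seealso [generate_space()], [generate_prices()]
#' @export
space_spec <- function(n_explored_chemicals = 81,
                       n_unexplored_chemicals = 369,
                       n_classes = 4,
                       class_proportions = c(0.35, 0.30, 0.20, 0.15),
                       n_descriptors = 40,
                       n_informative = 8,
                       n_conditions_per_chemical = c(8, 17),
                       class_shift = 6,
                       cluster_spread = 1,
                       noise_sd = 0.3,
                       condition_effect = c(0.35, -0.2, 0.5, -0.15, 0.1),
                       class_offset_sd = 0.5,
                       nonlinear = FALSE,
                       price_model = list(meanlog = 4, sdlog = 0.6,
                                          density_coupling = 0.8,
                                          unavailable_frac = 0.1),
                       seed = 1L) {
  spec <- list(
    n_explored_chemicals = as.integer(n_explored_chemicals),
    n_unexplored_chemicals = as.integer(n_unexplored_chemicals),
    n_classes = as.integer(n_classes),
    class_proportions = class_proportions,
    n_descriptors = as.integer(n_descriptors),
    n_informative = as.integer(n_informative),
    n_conditions_per_chemical = as.integer(n_conditions_per_chemical),
    class_shift = class_shift,
    cluster_spread = cluster_spread,
    noise_sd = noise_sd,
    condition_effect = condition_effect,
    class_offset_sd = class_offset_sd,
    nonlinear = isTRUE(nonlinear),
    price_model = price_model,
    seed = as.integer(seed)
  )
  class(spec) <- "space_spec"
  validate_space_spec(spec)
  spec
}

validate_space_spec <- function(spec) {
  chk <- function(ok, field, msg) {
    if (!ok) stop("invalid space_spec field '", field, "': ", msg,
                  call. = FALSE)
  }
  counts <- c("n_explored_chemicals", "n_unexplored_chemicals", "n_classes",
              "n_descriptors", "n_informative")
  for (f in counts) {
    chk(length(spec[[f]]) == 1 && is.finite(spec[[f]]) && spec[[f]] >= 1,
        f, "must be a positive count")
  }
  chk(spec$n_informative <= spec$n_descriptors, "n_informative",
      "cannot exceed n_descriptors")
  chk(spec$n_descriptors >= spec$n_informative + 4, "n_descriptors",
      "must be at least n_informative + 4 (redundant + near-constant columns)")
  chk(length(spec$class_proportions) == spec$n_classes, "class_proportions",
      "length must equal n_classes")
  chk(all(spec$class_proportions > 0), "class_proportions",
      "must be positive")
  chk(length(spec$n_conditions_per_chemical) == 2 &&
        all(spec$n_conditions_per_chemical >= 1) &&
        spec$n_conditions_per_chemical[1] <= spec$n_conditions_per_chemical[2],
      "n_conditions_per_chemical", "must be an increasing positive range")
  chk(spec$class_shift >= 0, "class_shift", "must be non-negative")
  chk(spec$cluster_spread > 0, "cluster_spread", "must be positive")
  chk(spec$noise_sd >= 0, "noise_sd", "must be non-negative")
  chk(length(spec$condition_effect) == 5, "condition_effect",
      "must have length 5 (one per eluent descriptor)")
  invisible(spec)
}

# Largest-remainder allocation of n items to proportions p (sums to n).
largest_remainder <- function(n, p) {
  p <- p / sum(p)
  quota <- n * p
  sizes <- floor(quota)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(quota - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1
  }
  as.integer(sizes)
}

# Fixed grid of plausible negative-mode mobile-phase conditions; row 1 is
# the reference condition assigned to unexplored chemicals.
eluent_condition_grid <- function() {
  grid <- expand.grid(pH = c(2.7, 3.5, 5.0, 7.0, 8.0, 9.0),
                      nh4 = c(0, 1),
                      organic = c(0.2, 0.5, 0.8))
  # polarity/viscosity/surface tension track the organic modifier fraction
  data.frame(
    pH = grid$pH,
    nh4 = grid$nh4,
    polarity = round(10.2 - 4.9 * grid$organic, 3),
    viscosity = round(1.0 - 0.55 * grid$organic, 3),
    surface_tension = round(72 - 49 * grid$organic, 2)
  )
}

#' Generate a synthetic explored/unexplored chemical space
#'
#' Draws explored chemicals from a single Gaussian region of descriptor
#' space and unexplored chemicals from `n_classes` Gaussian clusters whose
#' centers sit `class_shift` x `cluster_spread` away from the explored
#' center in random directions, so nearest-neighbor distances from the
#' unexplored to the explored space stochastically exceed within-explored
#' distances. The response is
#'
#' \deqn{y = \beta \cdot d_{informative} + \delta_{class} +
#'   \gamma \cdot e + \epsilon, \quad \epsilon \sim N(0, noise\_sd^2)}
#'
#' where `e` are the standardized eluent descriptors, plus pairwise
#' products of the first informative descriptors when `nonlinear = TRUE`.
#' Each explored chemical is replicated across a random draw of the eluent
#' condition grid; unexplored chemicals carry one instance each under the
#' reference condition.
#'
#' The descriptor block contains, besides the informative and pure-noise
#' columns, two nearly collinear copies of informative descriptors (fodder
#' for the correlation filter) and two near-constant columns that are
#' constant in the explored space but vary in some unexplored classes
#' (fodder for the near-zero-variance filter, and for its reversal as
#' labeling adds variance).
#'
#' @param spec A [space_spec()].
#' @return A `synthetic_space` list with elements `instances` (data.frame:
#'   `chemical_id`, `class`, descriptor columns `d0001...`, eluent columns,
#'   `logIE`, `price`) and `truth` (generative parameters: `beta`,
#'   `class_offsets`, `class_centers`, `noise_sd`, `condition_effect`).
#' @export
generate_space <- function(spec) {
  stopifnot(inherits(spec, "space_spec"))
  validate_space_spec(spec)
  set.seed(spec$seed)

  p <- spec$n_descriptors
  p_inf <- spec$n_informative
  n_red <- 2L   # collinear copies
  n_nzv <- 2L   # near-constant columns
  p_core <- p - n_red - n_nzv
  dnames <- sprintf("d%04d", seq_len(p))

  n_exp <- spec$n_explored_chemicals
  n_une <- spec$n_unexplored_chemicals
  class_sizes <- largest_remainder(n_une, spec$class_proportions)
  classes <- paste0("class", seq_len(spec$n_classes))

  # class centers: random unit directions scaled by class_shift
  centers <- matrix(0, spec$n_classes, p_core)
  for (k in seq_len(spec$n_classes)) {
    u <- stats::rnorm(p_core)
    centers[k, ] <- spec$class_shift * spec$cluster_spread * u / sqrt(sum(u^2))
  }

  # chemical-level core descriptors
  D_exp <- matrix(stats::rnorm(n_exp * p_core, sd = spec$cluster_spread),
                  n_exp, p_core)
  D_une <- do.call(rbind, lapply(seq_len(spec$n_classes), function(k) {
    sweep(matrix(stats::rnorm(class_sizes[k] * p_core,
                              sd = spec$cluster_spread),
                 class_sizes[k], p_core),
          2, centers[k, ], "+")
  }))
  D <- rbind(D_exp, D_une)
  n_chem <- nrow(D)

  # redundant columns: near-copies of the first informative descriptors
  red <- D[, seq_len(n_red), drop = FALSE] +
    matrix(stats::rnorm(n_chem * n_red, sd = 0.02 * spec$cluster_spread),
           n_chem, n_red)
  # near-constant columns: 0 in explored; vary only in the last class
  nzv <- matrix(0, n_chem, n_nzv)
  last_cls <- seq_len(n_chem) > (n_exp + sum(class_sizes[-spec$n_classes]))
  nzv[last_cls, ] <- matrix(stats::rnorm(sum(last_cls) * n_nzv,
                                         sd = spec$cluster_spread),
                            sum(last_cls), n_nzv)
  D_full <- cbind(D, red, nzv)
  colnames(D_full) <- dnames

  chem_ids <- sprintf("chem%04d", seq_len(n_chem))
  chem_class <- c(rep("explored", n_exp), rep(classes, class_sizes))

  # per-class response offsets (explored space is the reference level)
  class_offsets <- stats::rnorm(spec$n_classes, sd = spec$class_offset_sd)
  names(class_offsets) <- classes
  offset_of <- c(explored = 0, class_offsets)

  beta <- stats::rnorm(p_inf, sd = 0.5)

  # instance assembly
  grid <- eluent_condition_grid()
  cond_range <- spec$n_conditions_per_chemical
  n_cond <- c(sample(seq(cond_range[1], cond_range[2]), n_exp,
                     replace = TRUE),
              rep(1L, n_une))
  cond_idx <- unlist(lapply(seq_len(n_chem), function(i) {
    if (i <= n_exp) sample(nrow(grid), n_cond[i]) else 1L
  }))
  row_chem <- rep(seq_len(n_chem), n_cond)

  el <- grid[cond_idx, , drop = FALSE]
  el_std <- scale(as.matrix(grid))  # standardize over the design grid
  el_effect <- as.numeric(el_std[cond_idx, , drop = FALSE] %*%
                            spec$condition_effect)

  signal <- as.numeric(D_full[row_chem, seq_len(p_inf), drop = FALSE] %*% beta)
  if (spec$nonlinear) {
    a <- D_full[row_chem, 1]; b <- D_full[row_chem, 2]
    cc <- D_full[row_chem, min(3, p_inf)]
    signal <- signal + 0.4 * a * b - 0.3 * b * cc
  }
  noise <- stats::rnorm(length(row_chem), sd = spec$noise_sd)
  y <- signal + offset_of[chem_class[row_chem]] + el_effect + noise

  instances <- data.frame(
    chemical_id = chem_ids[row_chem],
    class = chem_class[row_chem],
    D_full[row_chem, , drop = FALSE],
    el,
    logIE = y,
    price = NA_real_,
    row.names = NULL,
    stringsAsFactors = FALSE
  )

  out <- list(
    instances = instances,
    truth = list(beta = beta, class_offsets = class_offsets,
                 class_centers = centers, noise_sd = spec$noise_sd,
                 condition_effect = spec$condition_effect,
                 informative = dnames[seq_len(p_inf)],
                 redundant = dnames[p_core + seq_len(n_red)],
                 near_constant = dnames[p_core + n_red + seq_len(n_nzv)]),
    spec = spec
  )
  class(out) <- "synthetic_space"
  out
}

#' @export
print.synthetic_space <- function(x, ...) {
  inst <- x$instances
  cat("synthetic chemical space:",
      length(unique(inst$chemical_id[inst$class == "explored"])),
      "explored chemicals /",
      length(unique(inst$chemical_id[inst$class != "explored"])),
      "unexplored chemicals in",
      length(setdiff(unique(inst$class), "explored")), "classes;",
      nrow(inst), "instances\n")
  invisible(x)
}

#' Attach vendor prices to the unexplored chemicals
#'
#' Assigns each unexplored chemical a lognormal price whose log-scale mean
#' increases with the chemical's d_NN=5 distance to the rest of the pool,
#' so chemicals in dense regions are systematically cheaper (cost-based
#' selection then under-samples sparse regions). A fraction of chemicals is
#' left unpriced (`NA`), standing in for compounds with no commercial
#' source.
#'
#' @param dataset A `synthetic_space` from [generate_space()].
#' @param price_model Overrides `dataset$spec$price_model`; see
#'   [space_spec()].
#' @param seed Seed for the price draws (defaults to `spec$seed + 1`).
#' @return The instance table with the `price` column filled for
#'   unexplored chemicals (constant across a chemical's instances).
#' @export
generate_prices <- function(dataset, price_model = NULL, seed = NULL) {
  stopifnot(inherits(dataset, "synthetic_space"))
  pm <- if (is.null(price_model)) dataset$spec$price_model else price_model
  if (is.null(seed)) seed <- dataset$spec$seed + 1L
  set.seed(seed)

  inst <- dataset$instances
  pool <- chemical_table(inst[inst$class != "explored", , drop = FALSE])
  n <- nrow(pool)
  dcols <- grep("^d[0-9]+$", names(pool), value = TRUE)
  X <- as.matrix(pool[, dcols, drop = FALSE])
  k <- min(5L, n - 1L)
  dnn <- knn_mean_distance(X, X, k = k, exclude_self = TRUE)
  z <- if (stats::sd(dnn) > 0) (dnn - mean(dnn)) / stats::sd(dnn) else dnn * 0

  logp <- pm$meanlog + pm$density_coupling * z +
    stats::rnorm(n, sd = pm$sdlog)
  price <- exp(logp)
  n_un <- round(pm$unavailable_frac * n)
  if (n_un > 0) price[sample(n, n_un)] <- NA_real_

  names(price) <- pool$chemical_id
  idx <- match(inst$chemical_id, names(price))
  inst$price <- ifelse(is.na(idx), NA_real_, price[idx])
  inst
}

#' Collapse an instance table to one row per chemical
#'
#' Molecular identity, not the eluent condition, defines a chemical's
#' position in descriptor space: every instance of a chemical carries the
#' same descriptor vector, so the first instance represents it.
#'
#' @param instances An instance table.
#' @return One row per unique `chemical_id`, in first-appearance order.
#' @export
chemical_table <- function(instances) {
  instances[!duplicated(instances$chemical_id), , drop = FALSE]
}

#' Molecular descriptor column names of an instance table
#' @param instances An instance table.
#' @return Columns matching the `d0001`-style descriptor naming.
#' @export
descriptor_columns <- function(instances) {
  grep("^d[0-9]+$", names(instances), value = TRUE)
}

#' Write an instance table and its generative truth to disk
#'
#' @param dataset A `synthetic_space`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written (`instances.csv`, `truth.txt`).
#' @export
write_space <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_space"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  inst_path <- file.path(dir, "instances.csv")
  utils::write.csv(dataset$instances, inst_path, row.names = FALSE)
  truth_path <- file.path(dir, "truth.txt")
  tr <- dataset$truth
  lines <- c(
    paste0("beta: ", paste(format(tr$beta, digits = 12), collapse = " ")),
    paste0("class_offsets: ",
           paste(names(tr$class_offsets), format(tr$class_offsets,
                                                 digits = 12),
                 sep = "=", collapse = " ")),
    paste0("noise_sd: ", format(tr$noise_sd, digits = 12)),
    paste0("condition_effect: ",
           paste(format(tr$condition_effect, digits = 12), collapse = " ")),
    paste0("informative: ", paste(tr$informative, collapse = " ")),
    paste0("seed: ", dataset$spec$seed)
  )
  writeLines(lines, truth_path)
  invisible(c(inst_path, truth_path))
}
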