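#' Shannon entropy of a class-count vector
#'
#' @param class_counts Non-negative counts with positive sum.
#' @return Entropy in bits, with the convention 0*log(0) = 0.
#' @export
shannon_entropy <- function(class_counts) {
  if (any(class_counts < 0)) stop_("negative counts")
  n <- sum(class_counts)
  if (n <= 0) stop_("all-zero counts")
  p <- class_counts[class_counts > 0] / n
  -sum(p * log2(p))
}

#' Minimum-description-length split acceptance test
#'
#' Decides whether a candidate binary split of a value-sorted sample is
#' worth its description cost: the split is accepted when its information
#' gain exceeds `(log2(N - 1) + delta) / N`, where
#' `delta = log2(3^k - 2) - (k*Ent(S) - k1*Ent(S1) - k2*Ent(S2))`.
#'
#' @param candidate A list with fields `N` (sample size), `k` (classes in
#'   S), `k1`, `k2` (classes in the two halves), `ent_S`, `ent_S1`,
#'   `ent_S2` (entropies, bits) and `gain` (information gain, bits); see
#'   [mdlp_discretize()] which constructs them.
#' @return `TRUE` if the split passes the MDL criterion.
#' @export
mdlp_accept <- function(candidate) {
  with(candidate, {
    if (N < 2) stop_("need at least two samples")
    delta <- log2(3^k - 2) - (k * ent_S - k1 * ent_S1 - k2 * ent_S2)
    gain > (log2(N - 1) + delta) / N
  })
}

# Class counts per run of tied values, plus candidate boundary positions.
# A boundary lies between two adjacent runs unless both runs are pure and
# of the same class (Fayyad's boundary-point restriction).
value_runs <- function(v, y, n_classes) {
  run_id <- cumsum(c(1L, diff(v) != 0))
  counts <- matrix(0L, nrow = max(run_id), ncol = n_classes)
  for (cl in seq_len(n_classes)) {
    t <- tabulate(run_id[y == cl], nbins = max(run_id))
    counts[, cl] <- t
  }
  counts
}

#' Supervised discretization by recursive MDL splitting
#'
#' Entropy-minimizing recursive binary splitting of a continuous variable
#' against a class label. Candidate cutpoints are midpoints between
#' adjacent distinct values where the class composition changes; a split is
#' kept only when [mdlp_accept()] holds and both sides retain at least
#' `min_bin` samples. An empty result means the variable earns no split
#' (the single-bin "ALL" scheme).
#'
#' @param values Numeric vector (no missing values; filter first).
#' @param labels Class labels, same length.
#' @param min_bin Minimum samples on each side of any cut.
#' @return Sorted numeric cutpoints (possibly length zero).
#' @export
mdlp_discretize <- function(values, labels, min_bin = 2) {
  if (length(values) != length(labels)) stop_("length mismatch")
  if (anyNA(values) || anyNA(labels)) stop_("missing values must be excluded by the caller")
  y <- as.integer(factor(labels))
  n_classes <- max(y, 0L)
  ord <- order(values)
  v <- values[ord]
  y <- y[ord]
  cuts <- numeric(0)

  recurse <- function(lo, hi) {
    n <- hi - lo + 1
    if (n < 2 * min_bin) return(invisible())
    vv <- v[lo:hi]
    yy <- y[lo:hi]
    runs <- value_runs(vv, yy, n_classes)
    if (nrow(runs) < 2) return(invisible())
    # class counts left of each run boundary (boundary b: runs 1..b left)
    cum <- apply(runs, 2, cumsum)
    cum <- matrix(cum, ncol = n_classes)
    tot <- cum[nrow(runs), ]
    nb <- nrow(runs) - 1
    left_n <- rowSums(cum)[seq_len(nb)]
    # boundary-point restriction
    pure_class <- function(cnt) {
      nz <- which(cnt > 0)
      if (length(nz) == 1) nz else 0L
    }
    pc <- apply(runs, 1, pure_class)
    is_boundary <- !(pc[seq_len(nb)] != 0 & pc[seq_len(nb)] == pc[2:(nb + 1)])
    feasible <- is_boundary & left_n >= min_bin & (n - left_n) >= min_bin
    if (!any(feasible)) return(invisible())
    ent <- function(cnt) if (sum(cnt) == 0) 0 else shannon_entropy(cnt)
    ent_S <- ent(tot)
    best <- NULL
    for (b in which(feasible)) {
      cl <- cum[b, ]
      cr <- tot - cl
      e1 <- ent(cl)
      e2 <- ent(cr)
      gain <- ent_S - (sum(cl) / n) * e1 - (sum(cr) / n) * e2
      if (is.null(best) || gain > best$gain + 1e-12) {
        run_ends <- cumsum(rowSums(runs))
        i <- run_ends[b]
        best <- list(cutpoint = (vv[i] + vv[i + 1]) / 2, b = b, i = i,
                     N = n, k = sum(tot > 0),
                     k1 = sum(cl > 0), k2 = sum(cr > 0),
                     ent_S = ent_S, ent_S1 = e1, ent_S2 = e2, gain = gain)
      }
    }
    if (!mdlp_accept(best)) return(invisible())
    cuts <<- c(cuts, best$cutpoint)
    recurse(lo, lo + best$i - 1)
    recurse(lo + best$i, hi)
    invisible()
  }

  if (length(v) >= 2 * min_bin && n_classes >= 2) recurse(1L, length(v))
  sort(cuts)
}

# ---- discretization schemes -------------------------------------------------

new_scheme <- function(entries, method) {
  structure(entries, method = method, class = "discretization_scheme")
}

#' @export
print.discretization_scheme <- function(x, ...) {
  cat("<discretization_scheme> method=", attr(x, "method"), ", ",
      length(x), " variables\n", sep = "")
  invisible(x)
}

cutpoint_labels <- function(cutpoints) {
  if (length(cutpoints) == 0) return("ALL")
  b <- c(-Inf, cutpoints, Inf)
  vapply(seq_len(length(b) - 1), function(i) {
    lo <- if (is.infinite(b[i])) "(-Inf" else paste0("[", format(b[i]))
    paste0(lo, ",", format(b[i + 1]), ")")
  }, "")
}

#' Clinical discretization scheme from reference intervals
#'
#' Builds the reference-interval scheme for every continuous registry
#' variable: two-sided intervals map to `below`/`within`/`above` (closed on
#' both ends), one-sided upper limits to `within`/`above` (`within` means
#' strictly below the limit, matching the "< x" notation). Age, which has
#' no reference interval, is binned by decades.
#'
#' @param registry A [bn_registry()].
#' @param age_cutpoints Decade cutpoints for age.
#' @return A `"discretization_scheme"` with method `"clinical"`.
#' @export
clinical_scheme <- function(registry, age_cutpoints = c(60, 70, 80)) {
  entries <- list()
  for (v in continuous_vars(registry)) {
    s <- registry[[v]]
    if (is.null(s$reference)) {
      entries[[v]] <- list(type = "cutpoints", cutpoints = age_cutpoints,
                           labels = cutpoint_labels(age_cutpoints))
    } else {
      one_sided <- if (is.list(s$reference)) {
        any(vapply(s$reference, function(b) is.na(b[1]), TRUE))
      } else {
        is.na(s$reference[1])
      }
      entries[[v]] <- list(type = "clinical", bounds = s$reference,
                           labels = if (one_sided) c("within", "above")
                           else c("below", "within", "above"))
    }
  }
  new_scheme(entries, "clinical")
}

#' Learn a data-driven (MDL) scheme from a cohort
#'
#' Runs [mdlp_discretize()] for each continuous variable against the
#' outcome label, using the records where both are observed.
#'
#' @param cohort A continuous [bn_cohort()] (typically a training fold).
#' @param min_bin Minimum samples per side of any cut.
#' @return A `"discretization_scheme"` with method `"mdl"`.
#' @export
learn_mdl_scheme <- function(cohort, min_bin = 2) {
  reg <- cohort$registry
  out_var <- outcome_var(reg)
  y <- cohort$data[[out_var]]
  entries <- list()
  for (v in continuous_vars(reg)) {
    x <- cohort$data[[v]]
    ok <- !is.na(x) & !is.na(y)
    cp <- mdlp_discretize(x[ok], y[ok], min_bin = min_bin)
    entries[[v]] <- list(type = "cutpoints", cutpoints = cp,
                         labels = cutpoint_labels(cp))
  }
  new_scheme(entries, "mdl")
}

#' Bundled data-driven scheme for the complete cohort
#'
#' The published MDL cutpoints for the 20-lab panel on complete data, plus
#' decade bins for age (which the published table omits).
#'
#' @param age_cutpoints Decade cutpoints used for age.
#' @return A `"discretization_scheme"` with method `"mdl"`.
#' @export
default_mdl_scheme <- function(age_cutpoints = c(60, 70, 80)) {
  path <- system.file("extdata", "mdl_scheme_complete_data.yaml",
                      package = "bnscreen", mustWork = TRUE)
  read_scheme(path, method = "mdl", age_cutpoints = age_cutpoints)
}

#' Read / write a cutpoint scheme file
#'
#' The file is a YAML map variable -> cutpoint list (empty list = single
#' "ALL" bin).
#'
#' @param path YAML file path.
#' @param method Scheme method tag.
#' @param age_cutpoints Added for `age` when the file lacks an entry.
#' @export
read_scheme <- function(path, method = "mdl", age_cutpoints = c(60, 70, 80)) {
  raw <- yaml::read_yaml(path)
  entries <- lapply(raw, function(cp) {
    cp <- sort(as.numeric(unlist(cp)))
    list(type = "cutpoints", cutpoints = cp, labels = cutpoint_labels(cp))
  })
  if (is.null(entries[["age"]]))
    entries[["age"]] <- list(type = "cutpoints", cutpoints = age_cutpoints,
                             labels = cutpoint_labels(age_cutpoints))
  new_scheme(entries, method)
}

#' @rdname read_scheme
#' @param scheme A `"discretization_scheme"` whose entries are cutpoints.
#' @export
write_scheme <- function(scheme, path) {
  raw <- lapply(scheme, function(e) {
    if (e$type != "cutpoints")
      stop_("only cutpoint schemes have a file representation")
    as.list(e$cutpoints)
  })
  yaml::write_yaml(raw, path)
  invisible(path)
}

# Map one numeric vector to state labels under a scheme entry.
# `sex` is needed for sex-specific clinical bounds.
apply_entry <- function(x, entry, sex = NULL, var = "") {
  out <- rep(NA_character_, length(x))
  obs <- !is.na(x)
  if (entry$type == "cutpoints") {
    idx <- findInterval(x[obs], entry$cutpoints) + 1L  # [c_{i-1}, c_i)
    out[obs] <- entry$labels[idx]
    return(out)
  }
  bounds <- entry$bounds
  if (is.list(bounds)) {
    if (is.null(sex)) stop_("variable '", var, "': sex-specific bounds need sex")
    if (any(obs & is.na(sex)))
      stop_("variable '", var, "': sex missing for a record with an observed value")
    lo <- rep(NA_real_, length(x))
    hi <- rep(NA_real_, length(x))
    for (s in names(bounds)) {
      lo[sex == s] <- bounds[[s]][1]
      hi[sex == s] <- bounds[[s]][2]
    }
  } else {
    lo <- rep(bounds[1], length(x))
    hi <- rep(bounds[2], length(x))
  }
  one_sided <- is.na(lo)
  res <- ifelse(one_sided,
                ifelse(x < hi, "within", "above"),
                ifelse(x < lo, "below", ifelse(x > hi, "above", "within")))
  out[obs] <- res[obs]
  out
}

#' Discretize a cohort under a scheme
#'
#' Maps every continuous column to its discrete states while leaving the
#' missingness mask untouched. The result carries a `states` attribute
#' listing the ordered state space of every model variable, which
#' downstream learning and inference use.
#'
#' @param cohort A continuous [bn_cohort()].
#' @param scheme A `"discretization_scheme"`.
#' @return A discretized [bn_cohort()].
#' @export
discretize_cohort <- function(cohort, scheme) {
  reg <- cohort$registry
  d <- cohort$data
  sex <- if ("sex" %in% names(d)) d$sex else NULL
  states <- list()
  for (v in registry_names(reg)) {
    s <- reg[[v]]
    if (s$kind == "continuous") {
      entry <- scheme[[v]]
      if (is.null(entry)) stop_("scheme lacks an entry for '", v, "'")
      d[[v]] <- apply_entry(d[[v]], entry, sex = sex, var = v)
      states[[v]] <- entry$labels
    } else {
      states[[v]] <- s$states
    }
  }
  out <- bn_cohort(reg, d, validate = FALSE)
  attr(out, "states") <- states
  attr(out, "truth") <- attr(cohort, "truth")
  out
}

#' Discretize a single record under a clinical scheme
#'
#' Record-level counterpart of [discretize_cohort()] restricted to
#' reference-interval schemes. The record is a one-row data frame (or named
#' list) with the registry's columns.
#'
#' @param record One patient record.
#' @param registry A [bn_registry()].
#' @param scheme A clinical `"discretization_scheme"`.
#' @return The record with continuous values replaced by states.
#' @export
apply_clinical_scheme <- function(record, registry, scheme) {
  if (attr(scheme, "method") != "clinical") stop_("scheme method is not 'clinical'")
  discretize_record(record, registry, scheme)
}

#' Discretize a single record under a cutpoint scheme
#'
#' @inheritParams apply_clinical_scheme
#' @param scheme An MDL (cutpoint) `"discretization_scheme"`.
#' @export
apply_cutpoint_scheme <- function(record, registry, scheme) {
  if (attr(scheme, "method") != "mdl") stop_("scheme method is not 'mdl'")
  discretize_record(record, registry, scheme)
}

discretize_record <- function(record, registry, scheme) {
  rec <- as.data.frame(record, stringsAsFactors = FALSE)
  sex <- if ("sex" %in% names(rec)) rec$sex else NULL
  for (v in continuous_vars(registry)) {
    if (!v %in% names(rec)) next
    rec[[v]] <- apply_entry(as.numeric(rec[[v]]), scheme[[v]], sex = sex, var = v)
  }
  rec
}

# Ordered state spaces of a discretized cohort.
cohort_states <- function(cohort) {
  st <- attr(cohort, "states")
  if (is.null(st)) stop_("cohort is not discretized (no states attribute)")
  st
}
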