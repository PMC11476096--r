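#' Batch descriptor extraction over a cohort
#'
#' Accepts a directory of images, a manifest `data.frame` with columns
#' `path` and `image_id` (and optionally `group`), or a named list of
#' in-memory images (names become `image_id`s, with an optional parallel
#' `groups` vector). Rows are sorted by `image_id` so repeated runs are
#' byte-identical. Per-image failures are collected — not silently
#' dropped — and reported via the `"failures"` attribute and a warning.
#'
#' @param x Directory path, manifest data frame, or named list of images.
#' @param config A [pipeline_config()].
#' @param groups Optional group labels, parallel to a list input.
#' @return A `data.frame` (class `descriptor_table`) with columns
#'   `image_id`, `group`, `activity`, `mobility`, `complexity`; attribute
#'   `config` holds the configuration fingerprint, attribute `failures` a
#'   data frame of failed images and messages.
#' @export
batch_descriptors <- function(x, config = pipeline_config(),
                              groups = NULL) {
  if (is.character(x) && length(x) == 1L) {
    if (!dir.exists(x)) input_error(sprintf("no such directory: '%s'", x))
    manifest_path <- file.path(x, "manifest.csv")
    if (file.exists(manifest_path)) {
      man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
      man$path <- ifelse(file.exists(man$path), man$path,
                         file.path(x, basename(man$path)))
      return(batch_descriptors(man, config))
    }
    files <- list.files(x, pattern = "\\.(png|jpe?g|pgm|pnm|ppm)$",
                        ignore.case = TRUE, full.names = TRUE)
    if (length(files) == 0L) {
      input_error(sprintf("no readable images found in '%s'", x))
    }
    man <- data.frame(path = files,
                      image_id = tools::file_path_sans_ext(basename(files)),
                      group = NA_character_, stringsAsFactors = FALSE)
    return(batch_descriptors(man, config))
  }

  if (is.data.frame(x)) {
    if (!all(c("path", "image_id") %in% names(x))) {
      input_error("manifest needs 'path' and 'image_id' columns")
    }
    if (anyDuplicated(x$image_id)) input_error("duplicate image_id values")
    inputs <- as.list(x$path)
    ids <- x$image_id
    grp <- if ("group" %in% names(x)) x$group else rep(NA_character_,
                                                       nrow(x))
  } else if (is.list(x)) {
    if (is.null(names(x)) || anyDuplicated(names(x))) {
      input_error("list input must have unique names (image ids)")
    }
    inputs <- x
    ids <- names(x)
    grp <- if (is.null(groups)) rep(NA_character_, length(x)) else groups
  } else {
    input_error("'x' must be a directory, manifest data frame, or list")
  }

  rows <- vector("list", length(inputs))
  fails <- list()
  for (i in seq_along(inputs)) {
    d <- tryCatch(
      hjorth_descriptors(inputs[[i]], config, image_id = ids[i],
                         group = grp[i]),
      error = function(e) e)
    if (inherits(d, "error")) {
      fails[[length(fails) + 1L]] <- data.frame(
        image_id = ids[i], message = conditionMessage(d),
        stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- data.frame(image_id = ids[i], group = grp[i],
                              activity = d$activity, mobility = d$mobility,
                              complexity = d$complexity,
                              stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(tab) || nrow(tab) == 0L) {
    input_error("descriptor extraction failed for every image")
  }
  tab <- tab[order(tab$image_id), , drop = FALSE]
  rownames(tab) <- NULL
  failures <- if (length(fails)) do.call(rbind, fails) else
    data.frame(image_id = character(0), message = character(0))
  if (nrow(failures) > 0L) {
    warning(sprintf("%d image(s) failed descriptor extraction: %s",
                    nrow(failures),
                    paste(failures$image_id, collapse = ", ")))
  }
  structure(tab, class = c("descriptor_table", "data.frame"),
            config = config_fingerprint(config), failures = failures)
}

#' Write a descriptor table as CSV with a JSON config sidecar
#'
#' @param table A `descriptor_table` from [batch_descriptors()].
#' @param path Output CSV path; the sidecar is written as
#'   `<path>.config.json`.
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  jsonlite::write_json(
    list(config = attr(table, "config") %||% "unknown",
         n_images = nrow(table),
         failures = attr(table, "failures")),
    paste0(path, ".config.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a descriptor table CSV
#'
#' @param path CSV with columns `image_id`, `group`, `activity`,
#'   `mobility`, `complexity`.
#' @return A `descriptor_table` data frame.
#' @export
read_descriptor_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "group", "activity", "mobility", "complexity")
  if (!all(need %in% names(tab))) {
    input_error(sprintf("descriptor table '%s' lacks columns: %s", path,
                        paste(setdiff(need, names(tab)), collapse = ", ")))
  }
  structure(tab, class = c("descriptor_table", "data.frame"))
}

#' Full rank-based group comparison of a descriptor table
#'
#' Mirrors the statistical workflow used on the pollen cohorts: per
#' descriptor, Shapiro-Wilk normality per group, Levene's test for
#' homogeneity of variance, Kruskal-Wallis rank ANOVA with rank sums and
#' rank averages, and Dunn's Bonferroni-adjusted post hoc matrix.
#'
#' @param table A `descriptor_table` (or data frame) with a `group`
#'   column; at least 2 groups, each with at least 3 rows.
#' @param descriptors Which descriptor columns to analyze.
#' @param levene_center Passed to [levene()].
#' @return A `group_report` list, one entry per descriptor, each holding
#'   `shapiro` (per group), `levene`, `kruskal`, `ranks`, `posthoc`.
#' @export
compare_groups <- function(table,
                           descriptors = c("activity", "mobility",
                                           "complexity"),
                           levene_center = "mean") {
  tab <- as.data.frame(table)
  if (!"group" %in% names(tab) || all(is.na(tab$group))) {
    input_error("'table' must carry group labels")
  }
  if (anyNA(tab[descriptors])) {
    input_error("descriptor table contains missing values")
  }
  counts <- table(tab$group)
  if (length(counts) < 2L) {
    input_error("need at least 2 groups for comparison")
  }
  small <- names(counts)[counts < 3L]
  if (length(small)) {
    input_error(sprintf("group(s) below minimum size 3: %s",
                        paste(small, collapse = ", ")))
  }
  out <- lapply(descriptors, function(d) {
    sample <- grouped_sample(tab[[d]], tab$group, descriptor_name = d)
    shapiro <- lapply(split(tab[[d]], tab$group), shapiro_wilk)
    kw <- kruskal_wallis(sample)
    list(descriptor = d,
         shapiro = shapiro,
         levene = levene(sample, center = levene_center),
         kruskal = kw,
         ranks = kw$rank_summary,
         posthoc = dunn_posthoc(sample))
  })
  names(out) <- descriptors
  structure(list(results = out, group_sizes = as.integer(counts),
                 group_labels = names(counts), n = nrow(tab)),
            class = "group_report")
}

#' @export
print.group_report <- function(x, ...) {
  cat(sprintf("<group_report> %d images, groups: %s\n", x$n,
              paste(sprintf("%s (n=%d)", x$group_labels, x$group_sizes),
                    collapse = ", ")))
  for (res in x$results) {
    cat(sprintf("\n== %s ==\n", res$descriptor))
    print(res$ranks)
    print(res$kruskal)
    print(res$levene)
    print(res$posthoc)
  }
  invisible(x)
}

#' Render a group report as Markdown
#'
#' @param report A `group_report` from [compare_groups()].
#' @param path Optional file to write to.
#' @return The Markdown lines, invisibly if `path` given.
#' @export
report_markdown <- function(report, path = NULL) {
  ln <- c("# Group comparison report", "",
          sprintf("Images: %d; groups: %s", report$n,
                  paste(sprintf("%s (n=%d)", report$group_labels,
                                report$group_sizes), collapse = ", ")), "")
  for (res in report$results) {
    ln <- c(ln, sprintf("## %s", res$descriptor), "",
            "| Group | n | Rank sum | Rank average |",
            "|---|---|---|---|",
            sprintf("| %s | %d | %g | %.3f |", res$ranks$labels,
                    res$ranks$sizes, res$ranks$rank_sums,
                    res$ranks$rank_averages), "",
            sprintf("- Shapiro-Wilk per group: %s",
                    paste(sprintf("%s p=%.6g", names(res$shapiro),
                                  vapply(res$shapiro,
                                         function(s) s$p_value,
                                         numeric(1))), collapse = "; ")),
            sprintf("- Levene F(%d, %d) = %.6g, p = %.6g",
                    res$levene$df_between, res$levene$df_res,
                    res$levene$statistic, res$levene$p_value),
            sprintf("- Kruskal-Wallis H = %.4f (df = %d), p = %.6g",
                    res$kruskal$statistic, res$kruskal$df,
                    res$kruskal$p_value), "",
            "Dunn-Bonferroni adjusted p-values:", "")
    k <- length(res$posthoc$labels)
    ln <- c(ln,
            paste0("| | ", paste(res$posthoc$labels, collapse = " | "),
                   " |"),
            paste0("|", paste(rep("---", k + 1L), collapse = "|"), "|"))
    for (i in seq_len(k)) {
      cells <- vapply(seq_len(k), function(j) {
        if (i == j) "" else sprintf("%.6f", res$posthoc$p_adj[i, j])
      }, character(1))
      ln <- c(ln, paste0("| ", res$posthoc$labels[i], " | ",
                         paste(cells, collapse = " | "), " |"))
    }
    ln <- c(ln, "")
  }
  if (!is.null(path)) {
    writeLines(ln, path)
    return(invisible(ln))
  }
  ln
}

#' Render a group report as JSON
#'
#' @inheritParams report_markdown
#' @return JSON string, or invisibly when written to `path`.
#' @export
report_json <- function(report, path = NULL) {
  payload <- list(
    n = report$n,
    groups = Map(function(l, n) list(label = l, n = n),
                 report$group_labels, as.list(report$group_sizes)),
    descriptors = lapply(report$results, function(res) list(
      shapiro = lapply(res$shapiro, function(s)
        list(W = s$statistic, p = s$p_value)),
      levene = list(SS = res$levene$SS, df = res$levene$df_between,
                    MS = res$levene$MS, SS_res = res$levene$SS_res,
                    df_res = res$levene$df_res, MS_res = res$levene$MS_res,
                    F = res$levene$statistic, p = res$levene$p_value),
      kruskal_wallis = list(H = res$kruskal$statistic,
                            df = res$kruskal$df,
                            p = res$kruskal$p_value),
      ranks = list(labels = res$ranks$labels, sizes = res$ranks$sizes,
                   rank_sums = res$ranks$rank_sums,
                   rank_averages = res$ranks$rank_averages),
      dunn_bonferroni = list(labels = res$posthoc$labels,
                             z = res$posthoc$z,
                             p_adj = res$posthoc$p_adj)))
  )
  if (!is.null(path)) {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
    return(invisible(path))
  }
  jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, na = "null")
}

#' Leave-one-out nearest-centroid classification
#'
#' An intentionally simple, exploratory baseline for the classification
#' stage: each image is assigned to the group whose centroid is nearest
#' in (optionally z-scored) descriptor space, with the left-out image
#' excluded from centroid and scaling estimates. Ties are broken by group
#' order with a note. A descriptor with zero variance in a training fold
#' is dropped from that fold with a warning.
#'
#' @param table A `descriptor_table` with group labels; at least 2
#'   groups, each of size >= 2.
#' @param standardize Z-score descriptors using training-fold mean/sd
#'   (default `TRUE`).
#' @param descriptors Descriptor columns to use.
#' @return List with `confusion` (true x predicted), `accuracy`,
#'   `assignments` data frame, and `notes`.
#' @export
classify_nearest_centroid <- function(table, standardize = TRUE,
                                      descriptors = c("activity",
                                                      "mobility",
                                                      "complexity")) {
  tab <- as.data.frame(table)
  if (!"group" %in% names(tab) || anyNA(tab$group)) {
    input_error("'table' must carry complete group labels")
  }
  counts <- table(tab$group)
  if (length(counts) < 2L || any(counts < 2L)) {
    input_error("need >= 2 groups, each with >= 2 rows")
  }
  labels <- names(counts)
  X <- as.matrix(tab[descriptors])
  n <- nrow(X)
  pred <- character(n)
  notes <- character(0)
  warned_zero_var <- FALSE
  for (i in seq_len(n)) {
    tr <- X[-i, , drop = FALSE]
    trg <- tab$group[-i]
    keep <- rep(TRUE, ncol(tr))
    if (standardize) {
      mu <- colMeans(tr)
      sdv <- apply(tr, 2L, stats::sd)
      keep <- sdv > 0
      if (!all(keep) && !warned_zero_var) {
        warning(sprintf("dropping zero-variance descriptor(s): %s",
                        paste(descriptors[!keep], collapse = ", ")))
        warned_zero_var <- TRUE
      }
      tr <- sweep(sweep(tr[, keep, drop = FALSE], 2L, mu[keep]), 2L,
                  sdv[keep], "/")
      xi <- (X[i, keep] - mu[keep]) / sdv[keep]
    } else {
      xi <- X[i, ]
    }
    cents <- vapply(labels, function(l)
      colMeans(tr[trg == l, , drop = FALSE]), numeric(sum(keep)))
    cents <- matrix(cents, nrow = sum(keep),
                    dimnames = list(NULL, labels))
    dist2 <- colSums((cents - xi)^2)
    best <- which(dist2 == min(dist2))
    if (length(best) > 1L) {
      notes <- c(notes, sprintf(
        "tie for row %d broken in favour of '%s'", i, labels[best[1L]]))
    }
    pred[i] <- labels[best[1L]]
  }
  confusion <- table(true = tab$group, predicted = factor(pred,
                                                          levels = labels))
  list(confusion = confusion,
       accuracy = mean(pred == tab$group),
       assignments = data.frame(image_id = tab$image_id,
                                true = tab$group, predicted = pred,
                                stringsAsFactors = FALSE),
       notes = notes)
}

#' Export the 3D descriptor scatter as CSV
#'
#' Writes (activity, mobility, complexity, group) per image — the data
#' behind a 3D group-separation scatter plot — leaving plotting to the
#' caller.
#'
#' @param table A `descriptor_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_scatter <- function(table, path) {
  tab <- as.data.frame(table)
  utils::write.csv(
    tab[c("image_id", "group", "activity", "mobility", "complexity")],
    path, row.names = FALSE)
  invisible(path)
}
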