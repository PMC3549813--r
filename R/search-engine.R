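# File-based profile repository and batch search.
#
# Layout: <root>/profiles/<profile_id>.yaml (rank profiles serialized in the
# three-letter-keyword YAML format with score_type "rank"; a binary-origin
# fixed cutoff is carried in the pass-through key FQC and tier boundaries in
# TBN) plus <root>/index.tsv. Flat files keep the repository reproducible
# and dependency-free.

INDEX_COLS <- c("profile_id", "file", "profile_class", "library_type",
                "treatment", "n")

#' Build an on-disk profile repository
#'
#' Parses each input file (`.yaml`/`.yml` as three-letter-keyword profile
#' documents, `.tsv` as two-column score tables with default metadata),
#' converts it to a rank profile, and persists the collection under `root`.
#' Binary profiles (score type `"binary"`) are converted via their nonzero
#' scores as the hit set; continuous profiles via [to_rank_profile()].
#' Unparseable files are skipped with a warning and counted in the summary;
#' a duplicate profile id is an error naming both paths.
#'
#' @param profile_files Character vector of input file paths.
#' @param root Repository root directory (created; must not already contain
#'   an index).
#' @param tie_rule Tie rule used during rank conversion.
#' @return A `profile_repository` object; its `summary` entry counts
#'   profiles by class and library type and lists skipped files.
#' @export
build_repository <- function(profile_files, root,
                             tie_rule = c("lexicographic", "input_order")) {
  tie_rule <- match.arg(tie_rule)
  if (file.exists(file.path(root, "index.tsv")))
    stop("repository already exists at ", root)
  dir.create(file.path(root, "profiles"), recursive = TRUE,
             showWarnings = FALSE)
  index <- data.frame(profile_id = character(0), file = character(0),
                      profile_class = character(0),
                      library_type = character(0), treatment = character(0),
                      n = integer(0), stringsAsFactors = FALSE)
  skipped <- character(0)
  seen <- list() # profile_id -> source path
  for (path in profile_files) {
    fp <- tryCatch({
      if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
        read_profile_yaml(path)
      else
        read_tsv_scores(path, profile_id = tools_file_stem(path))
    }, error = function(e) {
      warning("skipping unparseable file ", path, ": ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(fp)) { skipped <- c(skipped, path); next }
    if (!is.null(seen[[fp$profile_id]]))
      stop("duplicate profile id '", fp$profile_id, "' in ", path,
           " (first seen in ", seen[[fp$profile_id]], ")")
    seen[[fp$profile_id]] <- path
    rp <- if (fp$score_type == "binary") {
      binary_to_rank_profile(names(fp$scores)[fp$scores != 0],
                             names(fp$scores), fp$profile_id,
                             tie_rule = tie_rule)
    } else {
      to_rank_profile(fp, tie_rule = tie_rule)
    }
    index <- rbind(index, store_rank_profile(root, rp, fp$profile_class,
                                             fp$library_type, fp$treatment))
  }
  write_index(root, index)
  repo <- open_repository(root)
  repo$summary <- list(
    n_profiles = nrow(index),
    by_class = table(index$profile_class),
    by_library = table(index$library_type),
    skipped = skipped)
  repo
}

tools_file_stem <- function(path) sub("\\.[^.]*$", "", basename(path))

store_rank_profile <- function(root, rp, profile_class, library_type,
                               treatment) {
  ranks <- seq_len(rp$n)
  names(ranks) <- rp$ordered_strains
  md <- list()
  if (!is.null(rp$fixed_query_cutoff))
    md$FQC <- as.character(rp$fixed_query_cutoff)
  if (!is.null(rp$tier_boundaries))
    md$TBN <- paste(rp$tier_boundaries, collapse = ",")
  fp <- fitness_profile(rp$profile_id,
                        stats::setNames(as.numeric(ranks), names(ranks)),
                        treatment = treatment, score_type = "rank",
                        polarity = "low_is_defect",
                        library_type = library_type,
                        profile_class = profile_class, metadata = md)
  rel <- file.path("profiles", paste0(sanitize_id(rp$profile_id), ".yaml"))
  write_profile_yaml(fp, file.path(root, rel))
  data.frame(profile_id = rp$profile_id, file = rel,
             profile_class = profile_class, library_type = library_type,
             treatment = treatment, n = rp$n, stringsAsFactors = FALSE)
}

sanitize_id <- function(id) gsub("[^A-Za-z0-9._-]", "_", id)

write_index <- function(root, index) {
  utils::write.table(index, file.path(root, "index.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

#' Open an existing repository
#'
#' @param root Repository root directory containing `index.tsv`.
#' @return A `profile_repository` object.
#' @export
open_repository <- function(root) {
  idx_path <- file.path(root, "index.tsv")
  if (!file.exists(idx_path)) stop("no repository index at ", idx_path)
  index <- utils::read.table(idx_path, sep = "\t", header = TRUE,
                             colClasses = c(rep("character", 5), "integer"),
                             stringsAsFactors = FALSE)
  if (!identical(names(index), INDEX_COLS))
    stop("corrupt repository index at ", idx_path)
  if (anyDuplicated(index$profile_id))
    stop("repository index contains duplicate profile ids")
  structure(list(root = root, index = index, cache = new.env(parent =
                                                               emptyenv())),
            class = "profile_repository")
}

#' @export
print.profile_repository <- function(x, ...) {
  cat("<profile_repository> ", x$root, "\n  ",
      nrow(x$index), " profiles\n", sep = "")
  if (nrow(x$index) > 0)
    print(table(class = x$index$profile_class,
                library = x$index$library_type))
  invisible(x)
}

#' Add an already-built rank profile to a repository
#'
#' Programmatic insertion path for rank profiles that do not originate from
#' a score file, e.g. tiered genetic profiles built with
#' [build_genetic_rank_profile()].
#'
#' @param repo A `profile_repository`.
#' @param rp A [rank_profile()].
#' @param profile_class,library_type,treatment Metadata for the index.
#' @return The updated, reopened repository.
#' @export
repo_add_rank_profile <- function(repo, rp,
                                  profile_class = "genetic_genetic",
                                  library_type = "homozygous",
                                  treatment = rp$profile_id) {
  stopifnot(inherits(repo, "profile_repository"),
            inherits(rp, "rank_profile"))
  if (rp$profile_id %in% repo$index$profile_id)
    stop("duplicate profile id '", rp$profile_id, "' already in repository")
  row <- store_rank_profile(repo$root, rp, profile_class, library_type,
                            treatment)
  write_index(repo$root, rbind(repo$index, row))
  open_repository(repo$root)
}

#' Load one rank profile from a repository
#'
#' @param repo A `profile_repository`.
#' @param profile_id Profile identifier present in the index.
#' @return A [rank_profile()].
#' @export
repo_get_profile <- function(repo, profile_id) {
  stopifnot(inherits(repo, "profile_repository"))
  if (!is.null(repo$cache[[profile_id]])) return(repo$cache[[profile_id]])
  row <- repo$index[repo$index$profile_id == profile_id, , drop = FALSE]
  if (nrow(row) == 0L)
    stop("profile id '", profile_id, "' not found in repository ",
         repo$root)
  fp <- read_profile_yaml(file.path(repo$root, row$file))
  ord <- order(fp$scores, names(fp$scores), method = "radix")
  fqc <- fp$metadata$FQC
  tbn <- fp$metadata$TBN
  rp <- rank_profile(
    fp$profile_id, names(fp$scores)[ord],
    fixed_query_cutoff = if (!is.null(fqc)) as.integer(fqc),
    tier_boundaries = if (!is.null(tbn))
      as.integer(strsplit(tbn, ",", fixed = TRUE)[[1]]))
  repo$cache[[profile_id]] <- rp
  rp
}

#' Search a repository with a query rank profile
#'
#' Compares the query against every retained target profile and returns one
#' hit per target, sorted by overlap significance (descending), then
#' Tanimoto score (descending), then target id. Two modes mirror the two
#' classic frontends: a user-supplied query profile (`query` given), or a
#' query drawn from the repository by id (`query_id` given), in which case
#' the query is never matched against itself.
#'
#' @param repo A `profile_repository`.
#' @param query A [rank_profile()] (user-profile mode), or `NULL`.
#' @param query_id A profile id present in the repository (database mode),
#'   or `NULL`. Exactly one of `query` / `query_id` must be given.
#' @param opts [optimizer_options()] applied to every comparison.
#' @param profile_class,library_type Optional filters on the targets.
#' @return A `data.frame` of hits with target metadata, the overlap
#'   statistics, and `p_db_bonferroni` (Bonferroni across the number of
#'   targets searched, reported but not used for sorting).
#' @export
search_repository <- function(repo, query = NULL, query_id = NULL,
                              opts = optimizer_options(),
                              profile_class = NULL, library_type = NULL) {
  stopifnot(inherits(repo, "profile_repository"))
  if (is.null(query) == is.null(query_id))
    stop("give exactly one of query (a rank profile) or query_id")
  exclude <- NULL
  if (!is.null(query_id)) {
    query <- repo_get_profile(repo, query_id) # errors if absent
    exclude <- query_id
  }
  idx <- repo$index
  if (!is.null(profile_class))
    idx <- idx[idx$profile_class %in% profile_class, , drop = FALSE]
  if (!is.null(library_type))
    idx <- idx[idx$library_type %in% library_type, , drop = FALSE]
  if (!is.null(exclude))
    idx <- idx[idx$profile_id != exclude, , drop = FALSE]
  if (nrow(idx) == 0L)
    stop("no target profiles after filtering")
  hits <- lapply(seq_len(nrow(idx)), function(r) {
    tp <- repo_get_profile(repo, idx$profile_id[r])
    res <- compare_profiles(query, tp, opts)
    data.frame(target_id = idx$profile_id[r],
               treatment = idx$treatment[r],
               profile_class = idx$profile_class[r],
               library_type = idx$library_type[r],
               i_star = res$i_star, j_star = res$j_star, m = res$m,
               n = res$n, p_value = res$p_value, log10_p = res$log10_p,
               p_bonferroni = res$p_bonferroni,
               significance = res$significance, tanimoto = res$tanimoto,
               no_signal = res$no_signal, stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  hits$p_db_bonferroni <- pmin(1, hits$p_value * nrow(hits))
  ord <- order(-hits$significance, -hits$tanimoto, hits$target_id,
               method = "radix")
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL
  class(hits) <- c("search_hits", "data.frame")
  hits
}

#' Two-way filtering of search hits
#'
#' Retains hits passing joint thresholds on the two similarity axes:
#' overlap significance (`-log10 p`) and Tanimoto overlap score.
#'
#' @param hits A `search_hits` data frame from [search_repository()].
#' @param min_significance,min_tanimoto Non-negative thresholds; a hit is
#'   kept when `significance >= min_significance` and
#'   `tanimoto >= min_tanimoto`.
#' @return The filtered hits, same columns and ordering.
#' @export
filter_two_way <- function(hits, min_significance = 0, min_tanimoto = 0) {
  stopifnot(min_significance >= 0, min_tanimoto >= 0)
  keep <- hits$significance >= min_significance &
    hits$tanimoto >= min_tanimoto
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scatter plot of hits in the two-way cutoff plane
#'
#' Plots each hit as a point at (Tanimoto score, significance), with
#' optional threshold lines, the standard view for choosing joint cutoffs.
#'
#' @param hits A `search_hits` data frame.
#' @param min_significance,min_tanimoto Optional thresholds drawn as dashed
#'   lines.
#' @param file Optional PNG path; if given the plot is written there.
#' @return Invisibly, the data frame of (tanimoto, significance) pairs.
#' @export
plot_two_way <- function(hits, min_significance = NULL, min_tanimoto = NULL,
                         file = NULL) {
  pts <- data.frame(tanimoto = hits$tanimoto,
                    significance = hits$significance)
  if (!is.null(file)) {
    grDevices::png(file, width = 800, height = 600)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(pts$tanimoto, pts$significance,
                 xlab = "Tanimoto overlap score",
                 ylab = expression(-log[10] ~ "p-value"),
                 main = "Two-way cutoff view", pch = 19,
                 col = grDevices::rgb(0.2, 0.4, 0.8, 0.6))
  if (!is.null(min_tanimoto))
    graphics::abline(v = min_tanimoto, lty = 2, col = "red")
  if (!is.null(min_significance))
    graphics::abline(h = min_significance, lty = 2, col = "red")
  invisible(pts)
}

#' Predict genetic interactions from a repository
#'
#' All-vs-all comparison of the repository's genetic-genetic profiles (each
#' unordered pair once); a pair is reported as a predicted genetic
#' interaction when its minimized overlap p-value and Tanimoto score pass
#' the thresholds (strict inequalities: `p < p_threshold`,
#' `tanimoto > tc_threshold`). The default thresholds are the stringent
#' operating point used for interaction calling (`p < 1e-10`,
#' `Tc > 0.1`). Extremely significant pairs whose linear p underflows are
#' compared on the log10 scale.
#'
#' @param repo A `profile_repository` with at least two genetic-genetic
#'   profiles.
#' @param p_threshold,tc_threshold Calling thresholds.
#' @param opts [optimizer_options()] applied to every comparison.
#' @return A `data.frame` with columns `gene1`, `gene2`, `tanimoto`,
#'   `p_value`, `log10_p`, `significance`, sorted by Tanimoto (descending)
#'   then p (ascending).
#' @export
predict_interactions <- function(repo, p_threshold = 1e-10,
                                 tc_threshold = 0.1,
                                 opts = optimizer_options()) {
  stopifnot(inherits(repo, "profile_repository"))
  ids <- repo$index$profile_id[repo$index$profile_class ==
                                 "genetic_genetic"]
  if (length(ids) < 2L)
    stop("repository holds fewer than two genetic_genetic profiles")
  ids <- sort(ids, method = "radix")
  pairs <- utils::combn(ids, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(c) {
    g1 <- pairs[1L, c]; g2 <- pairs[2L, c]
    res <- compare_profiles(repo_get_profile(repo, g1),
                            repo_get_profile(repo, g2), opts)
    data.frame(gene1 = g1, gene2 = g2, tanimoto = res$tanimoto,
               p_value = res$p_value, log10_p = res$log10_p,
               significance = res$significance, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  keep <- out$log10_p < log10(p_threshold) & out$tanimoto > tc_threshold
  out <- out[keep, , drop = FALSE]
  ord <- order(-out$tanimoto, out$log10_p, out$gene1, out$gene2,
               method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
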