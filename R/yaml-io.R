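# Profile YAML dialect: every key is a three-letter uppercase keyword.
# Required: PID TRT LIB CLS SCT POL DAT; optional: DOS PLT SRC CMT.
# Unknown three-letter keys pass through untouched (the schema is scalable).

REQUIRED_KEYS <- c("PID", "TRT", "LIB", "CLS", "SCT", "POL", "DAT")
OPTIONAL_KEYS <- c("DOS", "PLT", "SRC", "CMT")
CANONICAL_KEY_ORDER <- c("PID", "TRT", "DOS", "LIB", "CLS", "SCT", "POL",
                         "PLT", "SRC", "CMT", "DAT")

#' Read a fitness profile from a three-letter-keyword YAML document
#'
#' The profile serialization format is a flat YAML mapping whose keys are
#' exactly three uppercase letters: `PID` (profile id), `TRT` (treatment),
#' `DOS` (dose), `LIB` (library type), `CLS` (profile class), `SCT` (score
#' type), `POL` (polarity), `PLT` (platform), `SRC` (source), `CMT`
#' (comment) and `DAT` (the strain-to-score mapping). Keys outside this
#' vocabulary are preserved in the profile's metadata bag, so extended
#' documents round-trip losslessly.
#'
#' @param path File path or connection containing one YAML document.
#' @return A [fitness_profile()].
#' @seealso [write_profile_yaml()] for the inverse.
#' @export
read_profile_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!is.list(doc) || is.null(names(doc)))
    stop("profile YAML must be a keyword mapping at top level")
  keys <- names(doc)
  malformed <- keys[!grepl("^[A-Z]{3}$", keys)]
  if (length(malformed) > 0L)
    stop("malformed keyword(s) (must be three uppercase letters): ",
         paste(malformed, collapse = ", "))
  if (anyDuplicated(keys))
    stop("duplicate keyword(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  missing <- setdiff(REQUIRED_KEYS, keys)
  if (length(missing) > 0L)
    stop("missing required keyword(s): ", paste(missing, collapse = ", "))
  dat <- doc$DAT
  if (length(dat) == 0L) stop("DAT mapping is empty")
  if (is.null(names(dat)) || any(!nzchar(names(dat))))
    stop("DAT must map strain ids to scores")
  if (anyDuplicated(names(dat)))
    stop("duplicate strain(s) in DAT: ",
         paste(unique(names(dat)[duplicated(names(dat))]), collapse = ", "))
  scores <- vapply(dat, function(v) {
    v <- suppressWarnings(as.numeric(v))
    if (length(v) != 1L || is.na(v)) NA_real_ else v
  }, numeric(1))
  if (any(is.na(scores)))
    stop("non-numeric DAT value for strain(s): ",
         paste(names(scores)[is.na(scores)], collapse = ", "))
  extra <- doc[setdiff(keys, c(REQUIRED_KEYS, OPTIONAL_KEYS))]
  fitness_profile(
    profile_id = as.character(doc$PID),
    treatment = as.character(doc$TRT),
    dose = if (!is.null(doc$DOS)) as.character(doc$DOS),
    library_type = as.character(doc$LIB),
    profile_class = as.character(doc$CLS),
    score_type = as.character(doc$SCT),
    polarity = as.character(doc$POL),
    platform = as.character(doc$PLT %||% ""),
    scores = scores,
    metadata = c(
      extra,
      if (!is.null(doc$SRC)) list(SRC = as.character(doc$SRC)),
      if (!is.null(doc$CMT)) list(CMT = as.character(doc$CMT))))
}

#' Write a fitness profile as a three-letter-keyword YAML document
#'
#' Emits the document [read_profile_yaml()] inverts exactly. Keys are written
#' in a fixed canonical order (`PID, TRT, DOS, LIB, CLS, SCT, POL, PLT, SRC,
#' CMT`, then pass-through metadata keys sorted, then `DAT`), so two writes
#' of the same profile are byte-identical.
#'
#' @param profile A [fitness_profile()].
#' @param path Output file path or connection.
#' @return `path`, invisibly.
#' @export
write_profile_yaml <- function(profile, path) {
  stopifnot(inherits(profile, "fitness_profile"))
  if (!is.numeric(profile$scores))
    stop("profile '", profile$profile_id,
         "': only numeric scores are serializable")
  md <- profile$metadata
  extra_keys <- setdiff(names(md), c(REQUIRED_KEYS, OPTIONAL_KEYS))
  bad <- extra_keys[!grepl("^[A-Z]{3}$", extra_keys)]
  if (length(bad) > 0L)
    stop("metadata key(s) not three uppercase letters: ",
         paste(bad, collapse = ", "))
  doc <- list(PID = profile$profile_id, TRT = profile$treatment,
              DOS = profile$dose, LIB = profile$library_type,
              CLS = profile$profile_class, SCT = profile$score_type,
              POL = profile$polarity,
              PLT = if (nzchar(profile$platform)) profile$platform,
              SRC = md$SRC, CMT = md$CMT)
  doc <- doc[!vapply(doc, is.null, logical(1))]
  for (k in sort(extra_keys)) doc[[k]] <- md[[k]]
  doc$DAT <- as.list(profile$scores)
  yaml::write_yaml(doc, path, precision = 17L)
  invisible(path)
}

#' Read a two-column TSV score table
#'
#' Parses `strain<TAB>score` rows; lines starting with `#` are header or
#' comment lines and are skipped. Scores accept scientific notation and use
#' the decimal point regardless of locale.
#'
#' @param path TSV file path or connection.
#' @param profile_id,treatment,score_type,polarity,library_type,profile_class,dose,platform
#'   Profile metadata supplied by the caller (the file carries scores only).
#' @return A [fitness_profile()].
#' @export
read_tsv_scores <- function(path, profile_id = "query", treatment = "",
                            score_type = "z_score",
                            polarity = "low_is_defect",
                            library_type = "homozygous",
                            profile_class = "chemical_genetic",
                            dose = NULL, platform = "") {
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) stop("no score rows in ", path)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield < 2L))
    stop("line ", keep[which(nfield < 2L)[1L]],
         ": expected strain<TAB>score")
  strains <- vapply(parts, `[[`, character(1), 1L)
  raw <- vapply(parts, `[[`, character(1), 2L)
  scores <- suppressWarnings(as.numeric(raw))
  if (any(is.na(scores)))
    stop("line ", keep[which(is.na(scores))[1L]], ": non-numeric score '",
         raw[which(is.na(scores))[1L]], "'")
  dup <- duplicated(strains)
  if (any(dup))
    stop("line ", keep[which(dup)[1L]], ": duplicate strain '",
         strains[which(dup)[1L]], "'")
  names(scores) <- strains
  fitness_profile(profile_id, scores, treatment = treatment,
                  score_type = score_type, polarity = polarity,
                  library_type = library_type, profile_class = profile_class,
                  dose = dose, platform = platform)
}

#' Read a genetic-interaction TSV table
#'
#' Parses `query<TAB>array<TAB>class<TAB>source` rows with class one of
#' `SL`, `SD`, `PE`; `#`-lines are skipped.
#'
#' @param path TSV file path or connection.
#' @return An [interaction_records()] table.
#' @export
read_interaction_tsv <- function(path) {
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) stop("no interaction rows in ", path)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield < 3L))
    stop("line ", keep[which(nfield < 3L)[1L]],
         ": expected query<TAB>array<TAB>class[<TAB>source]")
  interaction_records(
    query_gene = vapply(parts, `[[`, character(1), 1L),
    array_gene = vapply(parts, `[[`, character(1), 2L),
    severity = vapply(parts, `[[`, character(1), 3L),
    source = vapply(parts, function(p) if (length(p) >= 4L) p[[4L]] else "",
                    character(1)))
}
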