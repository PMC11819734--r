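# Dataset bookkeeping: manifest validation, CSV I/O, and the stratified
# pretrain/finetune/test split by breed.

SPLIT_LEVELS <- c("pretrain", "finetune", "test")

#' Validate and normalise a dataset manifest
#'
#' A manifest is a data.frame with columns `path`, `breed`, `emotion`,
#' `split`.  Paths must be unique and breeds non-empty; emotion labels must
#' belong to [emotion_levels()] (aliases Affectionate/Exploring/Sadness/
#' Playing are normalised to Care/Seeking/Grief/Play) or be `NA`; rows
#' assigned to the finetune or test splits must carry an emotion label,
#' because labels are only needed to measure downstream performance.
#'
#' @param df A data.frame.
#' @return The validated manifest (class `dataset_manifest`).
#' @export
as_dataset_manifest <- function(df) {
  stopifnot(is.data.frame(df))
  for (col in c("path", "breed")) {
    if (!col %in% names(df)) {
      stop("manifest is missing required column `", col, "`", call. = FALSE)
    }
  }
  if (!"emotion" %in% names(df)) df$emotion <- NA_character_
  if (!"split" %in% names(df)) df$split <- NA_character_
  df <- df[, c("path", "breed", "emotion", "split")]
  df$path <- as.character(df$path)
  df$breed <- as.character(df$breed)
  df$emotion <- as.character(df$emotion)
  df$split <- as.character(df$split)
  df$emotion[!is.na(df$emotion) & df$emotion == ""] <- NA_character_
  df$split[!is.na(df$split) & df$split == ""] <- NA_character_
  if (anyDuplicated(df$path)) {
    stop("manifest paths must be unique (first duplicate: row ",
         which(duplicated(df$path))[1L], ")", call. = FALSE)
  }
  if (nrow(df) > 0 && any(is.na(df$breed) | df$breed == "")) {
    stop("manifest breeds must be non-empty (row ",
         which(is.na(df$breed) | df$breed == "")[1L], ")", call. = FALSE)
  }
  al <- emotion_aliases()
  hit <- !is.na(df$emotion) & df$emotion %in% names(al)
  df$emotion[hit] <- al[df$emotion[hit]]
  bad <- !is.na(df$emotion) & !(df$emotion %in% emotion_levels())
  if (any(bad)) {
    stop("unknown emotion label \"", df$emotion[which(bad)[1L]],
         "\" at row ", which(bad)[1L], call. = FALSE)
  }
  bad_split <- !is.na(df$split) & !(df$split %in% SPLIT_LEVELS)
  if (any(bad_split)) {
    stop("unknown split \"", df$split[which(bad_split)[1L]], "\" at row ",
         which(bad_split)[1L], call. = FALSE)
  }
  need_label <- !is.na(df$split) & df$split %in% c("finetune", "test")
  if (any(need_label & is.na(df$emotion))) {
    stop("rows in the finetune/test splits must carry an emotion label (row ",
         which(need_label & is.na(df$emotion))[1L], ")", call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("dataset_manifest", "data.frame")
  df
}

#' Read / write a dataset manifest CSV
#'
#' CSV dialect: UTF-8, comma-separated, header `path,breed,emotion,split`
#' required (`emotion` and `split` may be absent and default to unassigned);
#' paths are relative to the manifest's directory.  Writing then reading
#' yields an equal manifest.
#'
#' @param path CSV file path.
#' @return `read_manifest()` returns a `dataset_manifest`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such manifest: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = c("NA", ""))
  as_dataset_manifest(df)
}

#' @rdname read_manifest
#' @param manifest A `dataset_manifest`.
#' @export
write_manifest <- function(manifest, path) {
  manifest <- as_dataset_manifest(manifest)
  utils::write.csv(manifest, path, row.names = FALSE, na = "")
  invisible(path)
}

# Largest-remainder apportionment of `total` across strata with quotas
# proportional to `sizes`, capped elementwise by `cap`.
.apportion <- function(sizes, total, cap = sizes) {
  if (total == 0) return(integer(length(sizes)))
  quota <- sizes * total / sum(sizes)
  base <- pmin(floor(quota), cap)
  rem <- total - sum(base)
  if (rem > 0) {
    frac <- quota - floor(quota)
    frac[base >= cap] <- -Inf
    ord <- order(frac, decreasing = TRUE)
    for (i in ord) {
      if (rem == 0) break
      if (base[i] < cap[i]) { base[i] <- base[i] + 1L; rem <- rem - 1L }
    }
  }
  if (rem > 0) stop("apportionment infeasible: deficit of ", rem, call. = FALSE)
  as.integer(base)
}

#' Stratified pretrain/finetune/test split
#'
#' Partitions a manifest into pretrain/finetune/test sets with a seeded
#' shuffle inside each breed stratum, so every split preserves the breed
#' distribution to within one image per stratum.  Within each stratum counts
#' are `floor(fraction * n)` topped up by largest remainder; when
#' `target_totals` is supplied the per-stratum top-ups are instead chosen (by
#' largest-remainder apportionment of each split across strata, smallest
#' split first) so the grand totals hit the targets exactly — this reproduces
#' printed dataset bookkeeping such as 3374/396/159 out of 3,929, which is
#' not an exact 86/10/4% rounding.
#'
#' @param manifest A `dataset_manifest`.
#' @param fractions Numeric triple (pretrain, finetune, test) summing to 1.
#' @param seed Integer seed for the within-stratum shuffles.
#' @param target_totals Optional integer triple of exact split totals.
#' @return List with `manifest` (split column filled) and `plan`, a
#'   data.frame of per-breed counts per split.
#' @export
stratified_split <- function(manifest, fractions = c(0.86, 0.10, 0.04),
                             seed = 1L, target_totals = NULL) {
  manifest <- as_dataset_manifest(manifest)
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-9 ||
      any(fractions < 0)) {
    stop("`fractions` must be three non-negative numbers summing to 1",
         call. = FALSE)
  }
  n <- nrow(manifest)
  if (n == 0L) {
    plan <- data.frame(breed = character(0), pretrain = integer(0),
                       finetune = integer(0), test = integer(0))
    return(list(manifest = manifest, plan = plan))
  }
  breeds <- sort(unique(manifest$breed))
  sizes <- vapply(breeds, function(b) sum(manifest$breed == b), integer(1))
  counts <- matrix(0L, length(breeds), 3L,
                   dimnames = list(breeds, SPLIT_LEVELS))
  if (is.null(target_totals)) {
    for (s in seq_along(breeds)) {
      ns <- sizes[s]
      base <- floor(fractions * ns)
      rem <- ns - sum(base)
      if (rem > 0) {
        frac <- fractions * ns - base
        ord <- order(frac, decreasing = TRUE)
        base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
      }
      counts[s, ] <- as.integer(base)
    }
  } else {
    target_totals <- as.integer(target_totals)
    if (length(target_totals) != 3L || any(target_totals < 0)) {
      stop("`target_totals` must be three non-negative integers", call. = FALSE)
    }
    if (sum(target_totals) != n) {
      stop("infeasible `target_totals`: they sum to ", sum(target_totals),
           " but the manifest has ", n, " rows (deficit ",
           n - sum(target_totals), ")", call. = FALSE)
    }
    # allocate smallest splits first so caps never bind awkwardly
    remaining <- sizes
    ord <- order(target_totals)
    for (j in ord[1:2]) {
      a <- .apportion(sizes, target_totals[j], cap = remaining)
      counts[, j] <- a
      remaining <- remaining - a
    }
    counts[, ord[3L]] <- as.integer(remaining)
    if (any(counts < 0)) {
      stop("infeasible `target_totals` for the given strata", call. = FALSE)
    }
  }
  rng <- rng_new(seed)
  split_col <- rep(NA_character_, n)
  for (s in seq_along(breeds)) {
    idx <- which(manifest$breed == breeds[s])
    idx <- rng_sample(rng, idx)
    k <- counts[s, ]
    assign_ <- rep(SPLIT_LEVELS, times = k)
    split_col[idx] <- assign_
  }
  manifest$split <- split_col
  # labels are only required on the supervised splits; keep validation happy
  # for unlabeled manifests by leaving emotion untouched (validated below
  # only when labels exist)
  need <- manifest$split %in% c("finetune", "test") & is.na(manifest$emotion)
  if (any(need)) {
    # allowed for unlabeled corpora: downstream training will refuse them,
    # but the split itself is pure bookkeeping
    class(manifest) <- c("dataset_manifest", "data.frame")
  } else {
    manifest <- as_dataset_manifest(manifest)
  }
  plan <- data.frame(breed = breeds,
                     pretrain = counts[, "pretrain"],
                     finetune = counts[, "finetune"],
                     test = counts[, "test"],
                     row.names = NULL, stringsAsFactors = FALSE)
  list(manifest = manifest, plan = plan)
}
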