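#' Pixelwise Cohen's kappa between two annotators
#'
#' Chance-corrected agreement between two three-class masks of the same
#' image, computed over the pixel grid:
#' \deqn{\kappa = \frac{N \sum_c |I_c \cap J_c| - \sum_c |I_c||J_c|}
#'   {N^2 - \sum_c |I_c||J_c|}}
#' with the sum over the three class channels and N the pixel count. This
#' equals the generic multi-category Cohen's kappa computed from the 3 x 3
#' pixel confusion matrix. Values range from -1 (perfect disagreement)
#' through 0 (chance-level) to 1 (perfect agreement).
#'
#' When the chance agreement is exactly 1 (both raters constant with
#' identical marginals) the statistic is undefined; identical masks return
#' 1 by convention and differing ones raise an error rather than silently
#' propagating NaN into matrix means.
#'
#' @param I,J [class_mask()] objects of identical shape.
#' @return A scalar in \[-1, 1\].
#' @examples
#' a <- class_mask(matrix(c(0L, 1L, 0L, 2L), 2, 2))
#' pairwise_kappa(a, a)
#' @export
pairwise_kappa <- function(I, J) {
  check_same_shape(I, J)
  li <- as_label_matrix(I); lj <- as_label_matrix(J)
  n <- length(li)
  agree <- 0; chance <- 0
  for (c in 0:2) {
    ic <- li == c; jc <- lj == c
    agree <- agree + sum(ic & jc)
    chance <- chance + sum(ic) * sum(jc)
  }
  denom <- n^2 - chance
  if (denom == 0) {
    if (identical(li, lj)) return(1)
    abort("kappa undefined: chance agreement is 1 but masks differ.")
  }
  (n * agree - chance) / denom
}

#' Pairwise kappa matrix over a panel of annotators
#'
#' Computes Cohen's kappa for every unordered pair of participants who
#' annotated the same image. Participants listed without a mask (they did
#' not mark this image) are kept in the matrix with missing entries, so
#' panel membership stays visible.
#'
#' @param participants A data frame with columns `participant_id`, `role`
#'   (`"student"` or `"expert"`) and a list-column `mask` ([class_mask()]
#'   or `NULL` when the participant skipped the image).
#' @return An `angio_agreement` object: the symmetric kappa matrix (unit
#'   diagonal, NA for missing participants) plus the roster.
#' @export
kappa_matrix <- function(participants) {
  stopifnot(all(c("participant_id", "role", "mask") %in%
                  names(participants)))
  if (!all(participants$role %in% c("student", "expert")))
    abort("roles must be 'student' or 'expert'.")
  have <- !vapply(participants$mask, is.null, logical(1))
  if (sum(have) < 2L)
    abort("need at least two participants with masks.")
  p <- nrow(participants)
  K <- matrix(NA_real_, p, p,
              dimnames = list(participants$participant_id,
                              participants$participant_id))
  diag(K)[have] <- 1
  idx <- which(have)
  for (a in seq_along(idx)) {
    for (b in seq_along(idx)) {
      if (b <= a) next
      i <- idx[a]; j <- idx[b]
      k <- pairwise_kappa(participants$mask[[i]], participants$mask[[j]])
      K[i, j] <- k; K[j, i] <- k
    }
  }
  structure(list(kappa = K, roster = tibble(
    participant_id = participants$participant_id,
    role = participants$role,
    annotated = have
  )), class = "angio_agreement")
}

#' @export
print.angio_agreement <- function(x, ...) {
  cat(sprintf("<angio_agreement> %d participants (%d annotated)\n",
              nrow(x$roster), sum(x$roster$annotated)))
  print(round(x$kappa, 3))
  invisible(x)
}

#' Group-mean kappa summaries
#'
#' Averages the pairwise kappas over student-student, expert-expert,
#' student-expert and all pairs, reporting mean, sample standard deviation
#' and pair count per group. Groups with no pairs (e.g. no experts in an
#' early phase) are reported with NA, mirroring the "-" entries of a phase
#' table.
#'
#' @param agreement An `angio_agreement` from [kappa_matrix()].
#' @return A tibble with columns group (`kappa_ss`, `kappa_ee`, `kappa_se`,
#'   `kappa_all`), mean, sd, n_pairs.
#' @export
group_mean_kappa <- function(agreement) {
  stopifnot(inherits(agreement, "angio_agreement"))
  K <- agreement$kappa
  roles <- agreement$roster$role
  p <- nrow(K)
  pairs <- which(upper.tri(K) & !is.na(K), arr.ind = TRUE)
  pair_tbl <- tibble(
    i = pairs[, 1], j = pairs[, 2],
    kappa = K[pairs],
    kind = dplyr::case_when(
      roles[pairs[, 1]] == "student" & roles[pairs[, 2]] == "student" ~ "kappa_ss",
      roles[pairs[, 1]] == "expert" & roles[pairs[, 2]] == "expert" ~ "kappa_ee",
      TRUE ~ "kappa_se"
    )
  )
  one <- function(values) {
    if (length(values) == 0L)
      return(tibble(mean = NA_real_, sd = NA_real_, n_pairs = 0L))
    tibble(mean = mean(values),
           sd = if (length(values) > 1L) sd(values) else NA_real_,
           n_pairs = length(values))
  }
  dplyr::bind_rows(
    dplyr::mutate(one(pair_tbl$kappa[pair_tbl$kind == "kappa_ss"]),
                  group = "kappa_ss"),
    dplyr::mutate(one(pair_tbl$kappa[pair_tbl$kind == "kappa_ee"]),
                  group = "kappa_ee"),
    dplyr::mutate(one(pair_tbl$kappa[pair_tbl$kind == "kappa_se"]),
                  group = "kappa_se"),
    dplyr::mutate(one(pair_tbl$kappa), group = "kappa_all")
  ) |>
    dplyr::select(dplyr::all_of(c("group", "mean", "sd", "n_pairs")))
}

#' Landis-Koch interpretation of a kappa value
#'
#' Bands: (0.0, 0.2\] slight, (0.2, 0.4\] fair, (0.4, 0.6\] moderate,
#' (0.6, 0.8\] substantial, (0.8, 1.0\] almost-perfect; values at or below
#' zero are reported as "poor/none".
#'
#' @param value A kappa value in \[-1, 1\] (vectorised).
#' @return Character band name(s).
#' @export
interpret_kappa <- function(value) {
  if (any(value < -1 | value > 1, na.rm = TRUE))
    abort("kappa must lie in [-1, 1].")
  cut(value,
      breaks = c(-1, 0, 0.2, 0.4, 0.6, 0.8, 1),
      labels = c("poor/none", "slight", "fair", "moderate", "substantial",
                 "almost-perfect"),
      include.lowest = TRUE, right = TRUE) |>
    as.character()
}

#' Read a panel of participant masks from disk
#'
#' Convenience loader for the agreement workflow: a directory of
#' single-channel mask PNGs named `<participant_id>.png` plus a roster CSV
#' with columns `participant_id` and `role`. Roster members without a mask
#' file are kept with a missing mask.
#'
#' @param dir Directory of mask PNGs.
#' @param roster_csv Path to the roster CSV.
#' @return A tibble suitable for [kappa_matrix()].
#' @export
read_participant_masks <- function(dir, roster_csv) {
  roster <- read.csv(roster_csv, stringsAsFactors = FALSE)
  stopifnot(all(c("participant_id", "role") %in% names(roster)))
  masks <- lapply(roster$participant_id, function(id) {
    f <- file.path(dir, paste0(id, ".png"))
    if (file.exists(f)) read_mask(f) else NULL
  })
  tibble(participant_id = roster$participant_id, role = roster$role,
         mask = masks)
}
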