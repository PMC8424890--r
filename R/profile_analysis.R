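# Averaged interaction profiles, contact frequencies, hotspots, differential
# profiles and outlier ranking over collections of interaction matrices.

check_aligned <- function(matrices) {
  stopifnot(length(matrices) >= 1L)
  fps <- unique(vapply(matrices, `[[`, "", "params_fingerprint"))
  if (length(fps) > 1L) {
    stop("matrices were built under different parameters: ",
         paste(fps, collapse = ", "), call. = FALSE)
  }
  axes <- lapply(matrices, function(m) m$residues$generic_number)
  if (length(unique(lapply(axes, identity))) > 1L) {
    stop("matrices do not share a position axis; run align_by_generic() first",
         call. = FALSE)
  }
  invisible(matrices)
}

#' Average aligned matrices into an interaction profile
#'
#' Every matrix cell is averaged over the collection and values lower than
#' the silencing threshold are set to zero (a value exactly equal to the
#' threshold survives). The denominator is either the full collection
#' (`all_matrices`, absent positions count as non-interacting) or only the
#' matrices in which the position is present (`present_only`).
#'
#' @param matrices list of aligned `sift2d_matrix` (see [align_by_generic()];
#'   matrices from identical complexes are already aligned).
#' @param threshold silencing threshold, default 0.3.
#' @param denominator_mode "all_matrices" (default) or "present_only".
#' @return a `sift2d_profile` with real-valued blocks, per-position support
#'   counts and the silencing threshold.
#' @export
average_profile <- function(matrices, threshold = 0.3,
                            denominator_mode = c("all_matrices",
                                                 "present_only")) {
  denominator_mode <- match.arg(denominator_mode)
  check_aligned(matrices)
  n <- length(matrices)
  npos <- length(matrices[[1L]]$blocks)
  support <- rowSums(vapply(matrices, function(m) m$residues$present,
                            logical(npos)) |> matrix(nrow = npos))
  blocks <- lapply(seq_len(npos), function(i) {
    acc <- Reduce(`+`, lapply(matrices, function(m) m$blocks[[i]] * 1.0))
    denom <- if (denominator_mode == "all_matrices") n else max(1L, support[i])
    avg <- acc / denom
    avg[avg < threshold] <- 0
    avg
  })
  structure(list(blocks = blocks,
                 residues = tibble::tibble(
                   chain = NA_character_, seqnum = NA_integer_,
                   insertion_code = "", name = NA_character_,
                   generic_number = matrices[[1L]]$residues$generic_number,
                   present = support > 0L),
                 complex_id = paste0("profile(", n, ")"),
                 params = matrices[[1L]]$params,
                 mask = matrices[[1L]]$mask,
                 params_fingerprint = matrices[[1L]]$params_fingerprint,
                 threshold = threshold, denominator_mode = denominator_mode,
                 support = as.integer(support), n_matrices = n),
            class = "sift2d_profile")
}

#' @export
print.sift2d_profile <- function(x, ...) {
  nz <- sum(vapply(x$blocks, function(b) sum(b) > 0, logical(1)))
  cat("<2D-SIFt profile over ", x$n_matrices, " matrices: ",
      length(x$blocks), " positions (", nz, " interacting), threshold ",
      x$threshold, ", denominator ", x$denominator_mode, ">\n", sep = "")
  invisible(x)
}

INTERACTION_CATEGORY <- c(Any = "any", BB = "any", SC = "any",
                          P = "polar", H = "hydrophobic", A = "acceptor",
                          D = "donor", C = "charged", R = "aromatic")

#' Contact frequency table over an aligned collection
#'
#' A position counts as interacting in a matrix when any cell of its block is
#' nonzero; the frequency is the fraction of matrices (per
#' `denominator_mode`) in which it interacts. The `cells` table additionally
#' reports, per (position, feature row, interaction column), the fraction of
#' matrices with that cell set, tagged with its interaction category
#' (charged, acceptor, donor, hydrophobic, aromatic, polar, any).
#'
#' @param matrices aligned list of `sift2d_matrix`.
#' @param denominator_mode "all_matrices" or "present_only".
#' @return a `sift2d_frequency`: list with tibbles `positions` (position,
#'   frequency) and `cells`.
#' @export
contact_frequency <- function(matrices,
                              denominator_mode = c("all_matrices",
                                                   "present_only")) {
  denominator_mode <- match.arg(denominator_mode)
  check_aligned(matrices)
  n <- length(matrices)
  axis <- matrices[[1L]]$residues$generic_number
  npos <- length(axis)
  present <- vapply(matrices, function(m) m$residues$present, logical(npos)) |>
    matrix(nrow = npos)
  denom <- if (denominator_mode == "all_matrices") rep(n, npos)
           else pmax(1L, rowSums(present))
  interacting <- vapply(matrices, function(m) {
    vapply(m$blocks, function(b) sum(b) > 0L, logical(1))
  }, logical(npos)) |> matrix(nrow = npos)
  positions <- tibble::tibble(position = axis,
                              frequency = rowSums(interacting) / denom)
  cell_hits <- Reduce(`+`, lapply(matrices, function(m) {
    vapply(m$blocks, function(b) as.numeric(b > 0), numeric(63L))
  }))
  cells <- tibble::tibble(
    position = rep(axis, each = 63L),
    feature = rep(FEATURE_TYPES, times = 9L * npos)[seq_len(63L * npos)],
    interaction = rep(rep(INTERACTION_TYPES, each = 7L), npos),
    frequency = as.numeric(cell_hits) / rep(denom, each = 63L))
  cells$category <- INTERACTION_CATEGORY[cells$interaction]
  cells <- cells[cells$frequency > 0, , drop = FALSE]
  structure(list(positions = positions, cells = cells,
                 denominator_mode = denominator_mode, n_matrices = n),
            class = "sift2d_frequency")
}

#' @export
print.sift2d_frequency <- function(x, ...) {
  cat("<sift2d contact frequencies over ", x$n_matrices, " matrices: ",
      nrow(x$positions), " positions, ",
      sum(x$positions$frequency > 0), " in contact>\n", sep = "")
  invisible(x)
}

#' Interaction hotspots
#'
#' Positions whose contact frequency strictly exceeds `min_fraction`
#' (the published filter keeps positions interacting in more than 30% of the
#' structures), ordered by descending frequency, ties broken by position.
#'
#' @param freq a `sift2d_frequency` from [contact_frequency()].
#' @param min_fraction strict lower bound on the contact fraction.
#' @return tibble (position, frequency) of hotspot positions.
#' @export
hotspots <- function(freq, min_fraction = 0.30) {
  pos <- freq$positions[freq$positions$frequency > min_fraction, ,
                        drop = FALSE]
  if (nrow(pos) == 0L) return(pos)
  axis_order <- match(pos$position, sort_generic(pos$position))
  pos[order(-pos$frequency, axis_order), , drop = FALSE]
}

#' Differential profile between two collections
#'
#' Classifies every position as common / unique to either profile / absent
#' (based on nonzero cells after silencing) and reports signed per-cell
#' differences `a - b` (e.g. agonist minus antagonist consensus).
#'
#' @param profile_a,profile_b `sift2d_profile` objects on the same axis and
#'   params.
#' @return a `sift2d_diff`: tibble `positions` (position, status) plus the
#'   list of signed difference blocks.
#' @export
differential_profile <- function(profile_a, profile_b) {
  if (!identical(profile_a$residues$generic_number,
                 profile_b$residues$generic_number)) {
    stop("profiles are not on the same position axis", call. = FALSE)
  }
  if (!identical(profile_a$params_fingerprint, profile_b$params_fingerprint)) {
    stop("profiles were built under different parameters", call. = FALSE)
  }
  axis <- profile_a$residues$generic_number
  in_a <- vapply(profile_a$blocks, function(b) sum(b) > 0, logical(1))
  in_b <- vapply(profile_b$blocks, function(b) sum(b) > 0, logical(1))
  status <- ifelse(in_a & in_b, "common",
                   ifelse(in_a, "unique_to_a",
                          ifelse(in_b, "unique_to_b", "absent")))
  diffs <- lapply(seq_along(axis), function(i) {
    profile_a$blocks[[i]] - profile_b$blocks[[i]]
  })
  structure(list(positions = tibble::tibble(position = axis, status = status),
                 blocks = diffs,
                 residues = profile_a$residues,
                 mask = profile_a$mask,
                 params_fingerprint = profile_a$params_fingerprint),
            class = "sift2d_diff")
}

#' @export
print.sift2d_diff <- function(x, ...) {
  tab <- table(factor(x$positions$status,
                      c("common", "unique_to_a", "unique_to_b", "absent")))
  cat("<sift2d differential profile: ", paste(names(tab), tab, sep = "=",
                                              collapse = " "), ">\n", sep = "")
  invisible(x)
}

#' Rank matrices by distance from a profile
#'
#' Each matrix is linearized (counts, not binary) and its Euclidean distance
#' to the profile's linearization computed; complexes far from the consensus
#' rank first. Ties are broken by complex id.
#'
#' @param matrices aligned list of `sift2d_matrix`.
#' @param profile a `sift2d_profile` on the same axis.
#' @return tibble (complex_id, distance, rank), descending by distance.
#' @export
outlier_scan <- function(matrices, profile) {
  check_aligned(c(matrices, list(profile)))
  pfp <- to_linear(profile, binary = FALSE)
  d <- vapply(matrices, function(m) {
    euclidean(to_linear(m, binary = FALSE), pfp)
  }, numeric(1))
  ids <- vapply(matrices, `[[`, "", "complex_id")
  ord <- order(-d, ids)
  tibble::tibble(complex_id = ids[ord], distance = d[ord],
                 rank = seq_along(ord))
}

#' Export a contact-frequency table as CSV or colored HTML
#'
#' The HTML rendering mirrors the published summary-table style: one row per
#' position, cells colored by interaction category (purple charged, yellow
#' acceptor, blue donor, green hydrophobic, orange aromatic, gray any) with
#' the color legend included.
#'
#' @param freq a `sift2d_frequency`.
#' @param path output path; format chosen by extension (.csv or .html).
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(freq, path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    merged <- merge(freq$cells, freq$positions, by = "position",
                    suffixes = c("_cell", "_position"))
    merged <- merged[order(-merged$frequency_position, merged$position), ]
    utils::write.csv(merged, path, row.names = FALSE)
    return(invisible(path))
  }
  colors <- c(charged = "#9467bd", acceptor = "#ffd92f", donor = "#1f77b4",
              hydrophobic = "#2ca02c", aromatic = "#ff7f0e", any = "#aaaaaa",
              polar = "#17becf")
  rows <- lapply(split(freq$cells, freq$cells$position), function(df) {
    pos <- df$position[1L]
    f <- freq$positions$frequency[freq$positions$position == pos]
    tags <- paste(sprintf(
      "<span style='background:%s;padding:1px 4px;margin:1px'>%s&times;%s</span>",
      colors[df$category], df$feature, df$interaction), collapse = " ")
    sprintf("<tr><td>%s</td><td>%.2f</td><td>%s</td></tr>", pos, f, tags)
  })
  legend <- paste(sprintf(
    "<span style='background:%s;padding:1px 6px'>%s</span>",
    colors, names(colors)), collapse = " ")
  html <- c("<html><head><meta charset='utf-8'/></head><body>",
            "<h3>Contact frequencies</h3>",
            sprintf("<p>Legend: %s</p>", legend),
            "<table border='1' cellspacing='0' cellpadding='3'>",
            "<tr><th>position</th><th>frequency</th><th>interactions</th></tr>",
            unlist(rows), "</table></body></html>")
  writeLines(html, path)
  invisible(path)
}
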