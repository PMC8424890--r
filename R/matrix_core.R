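# The InteractionMatrix data model: container, serialization, alignment,
# linearization and fingerprint similarity.

# deterministic polynomial rolling hash of the parameters + mask; a
# compatibility guard against mixing matrices built under different criteria
params_fingerprint <- function(params, mask) {
  payload <- paste(c(names(params), unlist(lapply(params, format, digits = 12)),
                     as.integer(mask)), collapse = "|")
  h <- 0
  for (b in utf8ToInt(payload)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Construct an interaction matrix object
#'
#' @param blocks list of 7x9 integer blocks, one per residue, in residue
#'   order.
#' @param residues tibble with columns chain, seqnum, insertion_code, name,
#'   generic_number, present.
#' @param complex_id identifier text.
#' @param params,mask the geometry parameters and incrementable mask the
#'   blocks were computed under (hashed into `params_fingerprint`).
#' @return object of class `sift2d_matrix`.
#' @export
interaction_matrix <- function(blocks, residues, complex_id = "complex",
                               params = geometry_params(),
                               mask = increment_mask()) {
  stopifnot(length(blocks) == nrow(residues))
  for (b in blocks) {
    if (!all(dim(b) == c(7L, 9L))) {
      stop("every residue block must be 7x9", call. = FALSE)
    }
  }
  blocks <- lapply(blocks, function(b) {
    dimnames(b) <- list(FEATURE_TYPES, INTERACTION_TYPES)
    storage.mode(b) <- "integer"
    b
  })
  structure(list(blocks = blocks, residues = residues,
                 complex_id = complex_id, params = params, mask = mask,
                 params_fingerprint = params_fingerprint(params, mask)),
            class = "sift2d_matrix")
}

#' @export
print.sift2d_matrix <- function(x, ...) {
  nz <- sum(vapply(x$blocks, function(b) sum(b) > 0, logical(1)))
  cat("<2D-SIFt matrix '", x$complex_id, "': ", length(x$blocks),
      " residues (", nz, " interacting), 7 x ", 9 * length(x$blocks),
      " fields, params ", x$params_fingerprint, ">\n", sep = "")
  invisible(x)
}

# residue display labels: generic number when present, else chain/seqnum
block_labels <- function(m) {
  gn <- m$residues$generic_number
  ifelse(!is.na(gn) & nzchar(gn), gn,
         paste0(m$residues$chain, "/", m$residues$seqnum,
                m$residues$insertion_code))
}

#' Linearize an interaction matrix to a fingerprint vector
#'
#' Traverses blocks in residue order, rows in canonical feature order and
#' columns in canonical interaction order, keeping only cells incrementable
#' under the matrix's mask. Binary mode maps any positive count to 1.
#'
#' @param matrix a `sift2d_matrix` (or `sift2d_profile`).
#' @param binary logical.
#' @return a `sift2d_fingerprint`: numeric `values`, `binary` flag,
#'   `index_map` tibble mapping positions to (residue, feature, interaction).
#' @export
to_linear <- function(matrix, binary = FALSE) {
  mask <- matrix$mask
  keep <- which(t(mask))  # column-order within row: transpose for row-major
  cells <- expand.grid(interaction = INTERACTION_TYPES,
                       feature = FEATURE_TYPES,
                       stringsAsFactors = FALSE)[keep, 2:1]
  labels <- block_labels(matrix)
  values <- unlist(lapply(matrix$blocks, function(b) as.numeric(t(b))[keep]),
                   use.names = FALSE)
  if (binary) values <- as.numeric(values > 0)
  index_map <- tibble::tibble(
    position = seq_along(values),
    residue = rep(labels, each = length(keep)),
    feature = rep(cells$feature, length(matrix$blocks)),
    interaction = rep(cells$interaction, length(matrix$blocks)))
  structure(list(values = values, binary = binary, index_map = index_map,
                 params_fingerprint = matrix$params_fingerprint),
            class = "sift2d_fingerprint")
}

#' @export
print.sift2d_fingerprint <- function(x, ...) {
  cat("<sift2d ", if (x$binary) "binary" else "count", " fingerprint: length ",
      length(x$values), ", ", sum(x$values > 0), " set positions>\n", sep = "")
  invisible(x)
}

check_compatible <- function(a, b) {
  if (length(a$values) != length(b$values)) {
    stop("fingerprint length mismatch (", length(a$values), " vs ",
         length(b$values), "; params ", a$params_fingerprint, " vs ",
         b$params_fingerprint, ")", call. = FALSE)
  }
}

#' Tanimoto similarity of two binary fingerprints
#'
#' `|a AND b| / |a OR b|`; two all-zero fingerprints compare as 1.0 (the
#' package's documented convention).
#'
#' @param a,b binary `sift2d_fingerprint` objects of equal length.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (!isTRUE(a$binary) || !isTRUE(b$binary)) {
    stop("tanimoto() requires binary fingerprints; use to_linear(binary = TRUE)",
         call. = FALSE)
  }
  check_compatible(a, b)
  union <- sum(a$values > 0 | b$values > 0)
  if (union == 0L) return(1.0)
  sum(a$values > 0 & b$values > 0) / union
}

#' Euclidean distance between two fingerprints
#'
#' @param a,b `sift2d_fingerprint` objects of equal length (binary or counts).
#' @return non-negative distance.
#' @export
euclidean <- function(a, b) {
  check_compatible(a, b)
  sqrt(sum((a$values - b$values)^2))
}

# ---- generic-number alignment ---------------------------------------------

# sort key of a GPCRdb label "HxNN[N]": helix, two-digit position, bulge digit
parse_generic <- function(x) {
  m <- regmatches(x, regexec("^([0-9]+)x([0-9]+)$", x))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    stop("malformed generic residue number(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  helix <- as.integer(vapply(m, `[`, "", 2L))
  pos <- vapply(m, `[`, "", 3L)
  primary <- as.integer(substr(pos, 1L, 2L))
  primary[nchar(pos) < 2L] <- as.integer(pos[nchar(pos) < 2L])
  bulge <- ifelse(nchar(pos) > 2L, as.integer(substring(pos, 3L)), 0L)
  data.frame(label = x, helix = helix, primary = primary, bulge = bulge)
}

sort_generic <- function(labels) {
  k <- parse_generic(labels)
  labels[order(k$helix, k$primary, k$bulge)]
}

#' Align interaction matrices on generic residue numbers
#'
#' Blocks carrying a generic number are placed on a common position axis (the
#' sorted union of all generic numbers); blocks without one are dropped from
#' the alignment with a warning. Positions a matrix does not cover are filled
#' with all-zero blocks flagged absent (`present = FALSE`), distinct from an
#' observed zero block.
#'
#' @param matrices list of `sift2d_matrix` sharing a params fingerprint.
#' @return list of aligned `sift2d_matrix` objects over the identical axis.
#' @export
align_by_generic <- function(matrices) {
  stopifnot(length(matrices) >= 1L)
  fps <- unique(vapply(matrices, `[[`, "", "params_fingerprint"))
  if (length(fps) > 1L) {
    stop("matrices were built under different parameters: ",
         paste(fps, collapse = ", "), call. = FALSE)
  }
  per_mat <- lapply(matrices, function(m) {
    gn <- m$residues$generic_number
    keep <- !is.na(gn) & nzchar(gn)
    if (any(!keep)) {
      warning("matrix '", m$complex_id, "': ", sum(!keep),
              " residue(s) without generic number dropped from alignment",
              call. = FALSE)
    }
    if (anyDuplicated(gn[keep])) {
      stop("matrix '", m$complex_id,
           "': duplicate generic number within one matrix", call. = FALSE)
    }
    list(m = m, gn = gn, keep = keep)
  })
  axis <- sort_generic(unique(unlist(lapply(per_mat, function(p) {
    p$gn[p$keep]
  }))))
  lapply(per_mat, function(p) {
    m <- p$m
    idx <- match(axis, p$gn)
    blocks <- lapply(idx, function(i) {
      if (is.na(i)) empty_block() else m$blocks[[i]]
    })
    residues <- tibble::tibble(
      chain = ifelse(is.na(idx), NA_character_, m$residues$chain[idx]),
      seqnum = ifelse(is.na(idx), NA_integer_, m$residues$seqnum[idx]),
      insertion_code = ifelse(is.na(idx), "", m$residues$insertion_code[idx]),
      name = ifelse(is.na(idx), NA_character_, m$residues$name[idx]),
      generic_number = axis,
      present = !is.na(idx))
    interaction_matrix(blocks, residues, complex_id = m$complex_id,
                       params = m$params, mask = m$mask)
  })
}

# ---- serialization ---------------------------------------------------------

MATRIX_FORMAT_VERSION <- 1L

#' Write an interaction matrix (or profile) to JSON
#'
#' Self-describing, versioned schema carrying the blocks, residue index,
#' geometry parameters, mask and params fingerprint; lossless round-trip via
#' [read_matrix()].
#'
#' @param matrix a `sift2d_matrix` or `sift2d_profile`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path) {
  is_profile <- inherits(matrix, "sift2d_profile")
  payload <- list(
    format = if (is_profile) "sift2d-profile" else "sift2d-matrix",
    version = MATRIX_FORMAT_VERSION,
    complex_id = matrix$complex_id,
    params = unclass(matrix$params),
    mask = lapply(seq_len(7), function(i) as.integer(matrix$mask[i, ])),
    params_fingerprint = matrix$params_fingerprint,
    residues = matrix$residues,
    blocks = lapply(matrix$blocks, function(b) {
      lapply(seq_len(7), function(i) unname(b[i, ]))
    }))
  if (is_profile) {
    payload$threshold <- matrix$threshold
    payload$denominator_mode <- matrix$denominator_mode
    payload$support <- matrix$support
    payload$n_matrices <- matrix$n_matrices
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(path)
}

#' Read an interaction matrix or profile written by [write_matrix()]
#'
#' @param path JSON file.
#' @return a `sift2d_matrix` or `sift2d_profile`.
#' @export
read_matrix <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyMatrix = FALSE)
  if (is.null(payload$format) ||
      !payload$format %in% c("sift2d-matrix", "sift2d-profile")) {
    stop("not a sift2d matrix/profile file: ", path, call. = FALSE)
  }
  if (payload$version != MATRIX_FORMAT_VERSION) {
    stop("unsupported sift2d format version ", payload$version,
         " (this build reads version ", MATRIX_FORMAT_VERSION, ")",
         call. = FALSE)
  }
  mask <- do.call(rbind, lapply(payload$mask, as.integer)) > 0
  dimnames(mask) <- list(FEATURE_TYPES, INTERACTION_TYPES)
  blocks <- lapply(seq_along(payload$blocks), function(k) {
    rows <- payload$blocks[[k]]
    b <- do.call(rbind, lapply(rows, as.numeric))
    if (is.null(b) || !all(dim(b) == c(7L, 9L))) {
      stop("corrupted block shape at block ", k, " of ", path, call. = FALSE)
    }
    dimnames(b) <- list(FEATURE_TYPES, INTERACTION_TYPES)
    b
  })
  residues <- tibble::as_tibble(payload$residues)
  if (nrow(residues) == 0L) {
    residues <- tibble::tibble(chain = character(), seqnum = integer(),
                               insertion_code = character(),
                               name = character(),
                               generic_number = character(),
                               present = logical())
  }
  residues$generic_number <- as.character(residues$generic_number)
  params <- do.call(geometry_params, payload$params)
  if (payload$format == "sift2d-matrix") {
    m <- interaction_matrix(blocks, residues, complex_id = payload$complex_id,
                            params = params, mask = mask)
  } else {
    m <- structure(list(blocks = blocks, residues = residues,
                        complex_id = payload$complex_id, params = params,
                        mask = mask,
                        params_fingerprint = params_fingerprint(params, mask),
                        threshold = payload$threshold,
                        denominator_mode = payload$denominator_mode,
                        support = as.integer(payload$support),
                        n_matrices = payload$n_matrices),
                   class = "sift2d_profile")
  }
  if (!identical(m$params_fingerprint, payload$params_fingerprint)) {
    stop("params fingerprint mismatch in ", path,
         ": file says ", payload$params_fingerprint, call. = FALSE)
  }
  m
}

#' Export a matrix or profile as a flat CSV table
#'
#' Rows are the 7 feature types; columns are residue x interaction type in
#' block order, labelled `<residue>:<interaction>`, matching the heat-map
#' layout.
#'
#' @param matrix a `sift2d_matrix` or `sift2d_profile`.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(matrix, path) {
  labels <- block_labels(matrix)
  wide <- do.call(cbind, matrix$blocks)
  colnames(wide) <- paste(rep(labels, each = 9L), INTERACTION_TYPES, sep = ":")
  df <- data.frame(feature = FEATURE_TYPES, wide, check.names = FALSE)
  header <- sprintf("# sift2d v%s matrix '%s' params %s",
                    as.character(utils::packageVersion("sift2d")),
                    matrix$complex_id, matrix$params_fingerprint)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
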