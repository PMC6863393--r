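# Synthetic genetic array scoring: plate/row/column normalization of
# colony sizes, log2 interaction scores against controls, hit calling,
# and rescue matrices.

#' Construct a colony plate
#'
#' A 384-format plate: 16 rows x 24 columns of colony sizes with a gene
#' per well (or NA for empty wells) and a per-well flag.
#'
#' @param df data.frame with columns `row` (1-16), `col` (1-24), `gene`
#'   (character, NA for empty), `size` (>= 0, finite) and optionally
#'   `flag` (`"ok"` or `"missing"`).
#' @param plate_id Plate identifier.
#' @return An object of class `colony_plate` (a data.frame).
#' @export
colony_plate <- function(df, plate_id = "plate1") {
  df <- as.data.frame(df)
  need <- c("row", "col", "gene", "size")
  if (!all(need %in% names(df))) {
    stop("plate needs columns ", paste(need, collapse = ", "))
  }
  if (is.null(df$flag)) df$flag <- ifelse(is.na(df$gene), "missing", "ok")
  if (nrow(df) != 384 ||
      !setequal(paste(df$row, df$col),
                paste(rep(1:16, each = 24), rep(1:24, times = 16)))) {
    stop("plate grid must cover 16 rows x 24 columns exactly once")
  }
  if (any(!is.finite(df$size)) || any(df$size < 0)) {
    stop("sizes must be finite and >= 0")
  }
  df$plate <- plate_id
  df <- df[order(df$row, df$col), c("plate", "row", "col", "gene", "size", "flag")]
  class(df) <- c("colony_plate", "data.frame")
  df
}

#' Normalize colony sizes per plate, row and column
#'
#' Sizes are divided by the plate median, then each row by its row
#' median, then each column by its column median (one pass, rows before
#' columns). Medians are taken over nonzero, non-missing wells only;
#' zero or missing wells keep their flags and are excluded from the
#' medians. A plate with under 50% nonzero growth is flagged (attribute
#' `excluded`) with a warning.
#'
#' @param plate A [colony_plate()].
#' @return The normalized plate.
#' @export
normalize_plate <- function(plate) {
  stopifnot(inherits(plate, "colony_plate"))
  present <- plate$flag == "ok"
  ok <- present & plate$size > 0
  if (sum(present) == 0 || sum(ok) / sum(present) < 0.5) {
    warning(sprintf("plate '%s': under 50%% growth; flagged", plate$plate[1]))
    attr(plate, "excluded") <- TRUE
    return(plate)
  }
  s <- plate$size
  s <- s / stats::median(s[ok])
  for (r in unique(plate$row)) {
    sel <- plate$row == r
    m <- stats::median(s[sel & ok])
    if (is.finite(m) && m > 0) s[sel] <- s[sel] / m
  }
  for (cc in unique(plate$col)) {
    sel <- plate$col == cc
    m <- stats::median(s[sel & ok])
    if (is.finite(m) && m > 0) s[sel] <- s[sel] / m
  }
  plate$size <- s
  attr(plate, "normalized") <- TRUE
  plate
}

#' Log2 interaction scores of query vs control plates
#'
#' Each plate is normalized with [normalize_plate()] (plates already
#' normalized, or flagged excluded, are respected). Normalized sizes of
#' a gene's replicate wells are averaged (mean over all ok wells across
#' plates) and the score is `log2(query mean / control mean)`. A gene
#' with query mean 0 is flagged lethal and carries a -Inf sentinel; a
#' gene absent from the controls is skipped with a message.
#'
#' @param query,control A [colony_plate()] or list of them.
#' @param pseudo Pseudocount added to both means before the ratio.
#' @return data.frame with `gene`, `score`, `n_replicates`, `lethal`.
#' @export
interaction_scores <- function(query, control, pseudo = 0) {
  q <- gene_means(query)
  c_ <- gene_means(control)
  missing_ctrl <- setdiff(q$gene, c_$gene)
  if (length(missing_ctrl) > 0) {
    message(sprintf(
      "%d gene(s) absent from controls skipped: %s",
      length(missing_ctrl), paste(utils::head(missing_ctrl, 5), collapse = ", ")
    ))
  }
  genes <- intersect(q$gene, c_$gene)
  qm <- q$mean[match(genes, q$gene)]
  cm <- c_$mean[match(genes, c_$gene)]
  lethal <- qm == 0
  score <- ifelse(lethal, -Inf, log2((qm + pseudo) / (cm + pseudo)))
  data.frame(
    gene = genes, score = score,
    n_replicates = q$n[match(genes, q$gene)],
    lethal = lethal, stringsAsFactors = FALSE
  )
}

#' Mean normalized size per gene over replicate wells and plates
#' @noRd
gene_means <- function(plates) {
  if (inherits(plates, "colony_plate")) plates <- list(plates)
  plates <- lapply(plates, function(p) {
    if (isTRUE(attr(p, "excluded"))) return(NULL)
    if (!isTRUE(attr(p, "normalized"))) p <- normalize_plate(p)
    if (isTRUE(attr(p, "excluded"))) return(NULL)
    p
  })
  plates <- Filter(Negate(is.null), plates)
  if (length(plates) == 0) stop("no usable plates")
  all <- do.call(rbind, lapply(plates, as.data.frame))
  all <- all[all$flag == "ok" & !is.na(all$gene), ]
  agg <- stats::aggregate(size ~ gene, data = all, FUN = mean)
  cnt <- stats::aggregate(size ~ gene, data = all, FUN = length)
  data.frame(gene = agg$gene, mean = agg$size, n = cnt$size,
             stringsAsFactors = FALSE)
}

#' Call synthetic-sick hits
#'
#' A gene is a hit when its score is strictly below the cutoff (a growth
#' reduction by more than the corresponding factor); lethal sentinels
#' (-Inf) are hits.
#'
#' @param scores [interaction_scores()] result.
#' @param cutoff Log2-ratio cutoff (default -1.0, a twofold reduction).
#' @return The scores data.frame with a logical `hit` column.
#' @export
call_hits <- function(scores, cutoff = -1.0) {
  scores$hit <- scores$score < cutoff
  attr(scores, "cutoff") <- cutoff
  scores
}

#' Assemble a rescue matrix
#'
#' Rows are genes, columns are rescue constructs; the first column
#' (`none`) reproduces the base query scores. A gene counts as rescued
#' by a construct when its score rises to or above the cutoff.
#'
#' @param base_scores [interaction_scores()] result for the unrescued
#'   query.
#' @param per_construct_scores Named list of [interaction_scores()]
#'   results, one per rescue construct.
#' @param cutoff Hit cutoff used for the rescue call (default -1.0).
#' @return A list of class `rescue_matrix`: `scores` (genes x
#'   constructs), `rescued` (logical, constructs only), `cutoff`.
#' @export
rescue_matrix <- function(base_scores, per_construct_scores, cutoff = -1.0) {
  genes <- base_scores$gene
  cols <- c("none", names(per_construct_scores))
  m <- matrix(NA_real_, length(genes), length(cols),
    dimnames = list(genes, cols)
  )
  m[, "none"] <- base_scores$score
  for (nm in names(per_construct_scores)) {
    s <- per_construct_scores[[nm]]
    m[, nm] <- s$score[match(genes, s$gene)]
  }
  rescued <- m[, -1, drop = FALSE] >= cutoff
  structure(
    list(scores = m, rescued = rescued, cutoff = cutoff),
    class = "rescue_matrix"
  )
}

#' Ground truth for a synthetic colony-plate experiment
#'
#' Multiplicative model for colony sizes: control size = plate effect x
#' row effect x column effect x lognormal noise; query wells are
#' additionally multiplied by the gene's true interaction fitness factor.
#'
#' @param genes Character vector of up to 384 gene names laid out
#'   row-major on the 16 x 24 grid (remaining wells empty).
#' @param plate_effects Numeric vector (> 0), one per replicate plate
#'   (recycled).
#' @param row_effects,col_effects Length-16 / length-24 positive effects.
#' @param interaction_factors Named numeric vector of true fitness
#'   factors per gene (default 1 = no interaction).
#' @param noise_sdlog Lognormal noise SD (sdlog; 0 = noise-free).
#' @param base_size Baseline colony size (arbitrary units).
#' @param seed RNG seed.
#' @return An object of class `plate_truth`.
#' @export
plate_truth <- function(genes, plate_effects = 1, row_effects = rep(1, 16),
                        col_effects = rep(1, 24),
                        interaction_factors = NULL, noise_sdlog = 0,
                        base_size = 100, seed = 1L) {
  if (length(genes) > 384) stop("at most 384 genes per plate")
  if (any(c(plate_effects, row_effects, col_effects) <= 0)) {
    stop("all effects must be > 0")
  }
  if (anyDuplicated(genes)) stop("exactly one gene per well")
  fac <- stats::setNames(rep(1, length(genes)), genes)
  if (!is.null(interaction_factors)) {
    unknown <- setdiff(names(interaction_factors), genes)
    if (length(unknown) > 0) stop("factors for unknown genes: ",
                                  paste(unknown, collapse = ", "))
    fac[names(interaction_factors)] <- interaction_factors
  }
  structure(
    list(
      genes = genes, plate_effects = plate_effects,
      row_effects = row_effects, col_effects = col_effects,
      interaction_factors = fac, noise_sdlog = noise_sdlog,
      base_size = base_size, seed = as.integer(seed)
    ),
    class = "plate_truth"
  )
}

#' Generate a synthetic colony experiment
#'
#' @param truth A [plate_truth()].
#' @param n_plates Number of replicate plate pairs (>= 1).
#' @return List with `query` and `control`: each a list of
#'   [colony_plate()] objects.
#' @export
gen_colony_experiment <- function(truth, n_plates = 1) {
  stopifnot(inherits(truth, "plate_truth"), n_plates >= 1)
  set.seed(truth$seed)
  gene_grid <- c(truth$genes, rep(NA_character_, 384 - length(truth$genes)))
  rows <- rep(1:16, each = 24)
  cols <- rep(1:24, times = 16)
  pe <- rep_len(truth$plate_effects, n_plates)
  query <- vector("list", n_plates)
  control <- vector("list", n_plates)
  for (p in seq_len(n_plates)) {
    base <- truth$base_size * pe[p] *
      truth$row_effects[rows] * truth$col_effects[cols]
    fac <- ifelse(is.na(gene_grid), 0, truth$interaction_factors[gene_grid])
    noise_c <- noise_q <- rep(1, 384)
    if (truth$noise_sdlog > 0) {
      noise_c <- exp(stats::rnorm(384, sd = truth$noise_sdlog))
      noise_q <- exp(stats::rnorm(384, sd = truth$noise_sdlog))
    }
    csize <- ifelse(is.na(gene_grid), 0, base * noise_c)
    qsize <- ifelse(is.na(gene_grid), 0, base * fac * noise_q)
    control[[p]] <- colony_plate(
      data.frame(row = rows, col = cols, gene = gene_grid, size = csize,
                 stringsAsFactors = FALSE),
      plate_id = sprintf("control_%02d", p)
    )
    query[[p]] <- colony_plate(
      data.frame(row = rows, col = cols, gene = gene_grid, size = qsize,
                 stringsAsFactors = FALSE),
      plate_id = sprintf("query_%02d", p)
    )
  }
  list(query = query, control = control)
}
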