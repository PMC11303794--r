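FINAL_STATES <- c("loss", "neutral", "gain", "LOH")
DETAILED_STATES <- c("loss_A", "loss_B", "loss_bal", "neutral", "gain",
                     "loh_A", "loh_B")

#' Default RDR x BAF combination rule table
#'
#' One row per (expression state, allelic state) pair, mapping the joint
#' probability mass to a detailed CNA state. Allele sides follow the B-allele
#' frequency: an allele-A-biased state (BAF toward 0) means haplotype B was
#' lost, and vice versa. `(loss, balanced)` is copy loss carrying the
#' whole-genome-duplication flag (balanced allelic ratios should not happen
#' with copy loss against a diploid baseline). The table is plain data so the
#' mapping can be audited or replaced without code changes.
#'
#' @param baf_states allelic state labels (5-state default or 3-state).
#' @return tibble with columns `rdr_state`, `baf_state`, `detailed`.
#' @export
default_combine_rules <- function(baf_states = BAF_STATES_5) {
  a_side <- grep("^A_", baf_states, value = TRUE)
  b_side <- grep("^B_", baf_states, value = TRUE)
  rules <- list(
    tibble::tibble(rdr_state = "neutral", baf_state = "balanced", detailed = "neutral"),
    tibble::tibble(rdr_state = "neutral", baf_state = a_side, detailed = "loh_B"),
    tibble::tibble(rdr_state = "neutral", baf_state = b_side, detailed = "loh_A"),
    tibble::tibble(rdr_state = "loss", baf_state = "balanced", detailed = "loss_bal"),
    tibble::tibble(rdr_state = "loss", baf_state = a_side, detailed = "loss_B"),
    tibble::tibble(rdr_state = "loss", baf_state = b_side, detailed = "loss_A"),
    tibble::tibble(rdr_state = "gain", baf_state = baf_states, detailed = "gain"))
  dplyr::bind_rows(rules)
}

DETAIL_LABELS <- c(loss_A = "loss-A", loss_B = "loss-B", loss_bal = "none",
                   neutral = "none", gain = "none", loh_A = "LOH-A",
                   loh_B = "LOH-B")

#' Combine expression and allelic posteriors into final CNA calls
#'
#' Forms the joint probability `q(r, b) = P_rdr(r) * P_baf(b)` per cell and
#' gene, routes each of the joint cells through the combination rule table,
#' and sums into a detailed 7-state tensor (loss-A, loss-B,
#' loss-balanced/WGD, neutral, gain, LOH-A, LOH-B) which collapses to the
#' four final states (loss, neutral, gain, LOH). Hard calls take the final
#' argmax with ties to neutral; `allele_detail` records the lost haplotype
#' for loss/LOH calls and `wgd_flags` marks entries whose dominant joint
#' cell is (loss, balanced).
#'
#' @param rdr gene-scale 3-state `state_tensor` (expression posterior).
#' @param baf gene-scale allelic `state_tensor` (mapped from bins with
#'   [bins_to_genes()]).
#' @param rules combination table (default [default_combine_rules()]).
#' @return object of class `cna_calls`: list with `P` (4-state tensor),
#'   `detailed` (7-state tensor), `calls`, `allele_detail`, `wgd_flags`.
#' @export
combine_modules <- function(rdr, baf, rules = NULL) {
  stopifnot(attr(rdr, "scale") == "gene", attr(baf, "scale") == "gene",
            all(dim(rdr)[1:2] == dim(baf)[1:2]))
  rdr_states <- tensor_states(rdr)
  baf_states <- tensor_states(baf)
  if (is.null(rules)) rules <- default_combine_rules(baf_states)
  n_c <- dim(rdr)[1]; n_g <- dim(rdr)[2]
  det <- array(0, dim = c(n_c, n_g, length(DETAILED_STATES)))
  best_joint <- matrix(-Inf, n_c, n_g)
  best_detail <- matrix(NA_integer_, n_c, n_g)
  for (r in seq_len(nrow(rules))) {
    ri <- match(rules$rdr_state[r], rdr_states)
    bi <- match(rules$baf_state[r], baf_states)
    di <- match(rules$detailed[r], DETAILED_STATES)
    if (is.na(ri) || is.na(bi)) stop("rule references unknown state")
    q <- rdr[, , ri, drop = TRUE] * baf[, , bi, drop = TRUE]
    q <- matrix(q, n_c, n_g)
    det[, , di] <- det[, , di] + q
    upd <- q > best_joint
    best_joint[upd] <- q[upd]
    best_detail[upd] <- di
  }
  detailed <- state_tensor(det, DETAILED_STATES, scale = "gene")
  P <- array(0, dim = c(n_c, n_g, 4))
  P[, , 1] <- det[, , 1] + det[, , 2] + det[, , 3]
  P[, , 2] <- det[, , 4]
  P[, , 3] <- det[, , 5]
  P[, , 4] <- det[, , 6] + det[, , 7]
  P <- state_tensor(P, FINAL_STATES, scale = "gene")
  calls <- apply_argmax(P, which(FINAL_STATES == "neutral"))
  # allele detail from the dominating detailed state, only on loss/LOH calls
  detail_argmax <- apply_argmax(detailed, which(DETAILED_STATES == "neutral"))
  allele_detail <- matrix(unname(DETAIL_LABELS[detail_argmax]), n_c, n_g)
  allele_detail[!(calls %in% c("loss", "LOH"))] <- "none"
  wgd_flags <- matrix(DETAILED_STATES[best_detail] == "loss_bal", n_c, n_g)
  structure(list(P = P, detailed = detailed, calls = calls,
                 allele_detail = allele_detail, wgd_flags = wgd_flags),
            class = "cna_calls")
}

#' @method print cna_calls
#' @export
print.cna_calls <- function(x, ...) {
  tab <- table(factor(x$calls, levels = FINAL_STATES))
  cat(sprintf("<cna_calls> %d cells x %d genes; calls: %s\n",
              nrow(x$calls), ncol(x$calls),
              paste(names(tab), as.integer(tab), sep = "=", collapse = " ")))
  invisible(x)
}

#' Whole-genome-duplication warning
#'
#' Copy loss with balanced allelic ratios should not happen against a
#' diploid baseline; widespread entries of that kind indicate the "neutral"
#' baseline is actually duplicated. For every annotated cell cluster, a gene
#' is implicated when at least `cell_frac_threshold` of the cluster's cells
#' carry the WGD flag there; a warning is raised when implicated genes
#' exceed `genome_frac_threshold` of the genome for any cluster.
#'
#' @param combined `cna_calls` from [combine_modules()].
#' @param cells cell annotation (clusters = `cell_type`).
#' @param genes gene annotation for the called genes (regions reported per
#'   chromosome arm).
#' @param cell_frac_threshold within-cluster cell fraction (default 0.5).
#' @param genome_frac_threshold genome fraction (default 0.05).
#' @return list with `warning` (logical), `report` (tibble: cluster, chrom,
#'   arm, n_genes implicated), `gene_frac` per cluster.
#' @export
wgd_warning <- function(combined, cells, genes,
                        cell_frac_threshold = 0.5,
                        genome_frac_threshold = 0.05) {
  clusters <- unique(cells$cell_type)
  rows <- list()
  gene_frac <- setNames(numeric(length(clusters)), clusters)
  for (cl in clusters) {
    in_cl <- cells$cell_type == cl
    frac <- colMeans(combined$wgd_flags[in_cl, , drop = FALSE])
    implicated <- frac >= cell_frac_threshold
    gene_frac[cl] <- mean(implicated)
    if (any(implicated)) {
      rows[[cl]] <- tibble::tibble(cluster = cl,
                                   chrom = as.character(genes$chrom[implicated]),
                                   arm = genes$arm[implicated]) |>
        dplyr::count(.data$cluster, .data$chrom, .data$arm, name = "n_genes")
    }
  }
  report <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(cluster = character(), chrom = character(),
                   arm = character(), n_genes = integer())
  warn <- any(gene_frac > genome_frac_threshold)
  if (warn) {
    warning("possible whole genome duplication: widespread loss calls with ",
            "balanced allelic ratios (see report)")
  }
  list(warning = warn, report = report, gene_frac = gene_frac)
}

#' Post-denoise: mask genes with a low aneuploid-cell proportion
#'
#' For each gene the aneuploid proportion is the fraction of cells whose
#' argmax state differs from the neutral/balanced state. A two-component
#' Gaussian mixture over these proportions separates background genes from
#' CNA genes; genes in the lower-mean component have their probability rows
#' replaced by the neutral one-hot. A manual proportion threshold can be
#' supplied instead. If the mixture is degenerate (e.g. all proportions
#' equal) nothing is masked and a warning is issued.
#'
#' @param tensor `state_tensor` of posteriors.
#' @param neutral_state neutral/balanced state label.
#' @param threshold optional manual proportion threshold (masks genes with
#'   proportion strictly below it).
#' @return list with `tensor` (masked), `mask` (logical per feature),
#'   `proportions` (per feature).
#' @export
post_denoise <- function(tensor, neutral_state = "balanced", threshold = NULL) {
  states <- tensor_states(tensor)
  ni <- which(states == neutral_state)
  stopifnot(length(ni) == 1L)
  calls <- apply_argmax(tensor, ni)
  prop <- colMeans(calls != neutral_state)
  if (!is.null(threshold)) {
    mask <- prop < threshold
  } else if (length(unique(round(prop, 10))) < 2L) {
    warning("aneuploid proportions are constant; no denoising applied")
    mask <- rep(FALSE, length(prop))
  } else {
    fit <- tryCatch(
      mclust::Mclust(prop, G = 2, modelNames = "V", verbose = FALSE),
      error = function(e) NULL)
    if (is.null(fit)) {
      fit <- tryCatch(
        mclust::Mclust(prop, G = 2, modelNames = "E", verbose = FALSE),
        error = function(e) NULL)
    }
    if (is.null(fit)) {
      warning("denoise GMM failed; no masking applied")
      mask <- rep(FALSE, length(prop))
    } else {
      low <- which.min(fit$parameters$mean)
      mask <- fit$classification == low
    }
  }
  if (any(mask)) {
    P <- unclass(tensor)
    P[, mask, ] <- 0
    P[, mask, ni] <- 1
    tensor <- state_tensor(P, states, scale = attr(tensor, "scale"))
  }
  list(tensor = tensor, mask = unname(mask), proportions = unname(prop))
}
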