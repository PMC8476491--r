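#' FamilySpec: parameters of the synthetic protein-family generator
#'
#' The generator draws site-specific amino-acid profiles from a symmetric
#' Dirichlet (small \code{alpha} gives conserved columns), samples
#' sequences independently per column from the profiles, optionally
#' injects gaps, and can build redundancy blocks (founders duplicated
#' with a per-site mutation rate) to emulate sampling bias in real
#' families. Because columns are independent, the true effect of any
#' substitution has the closed form
#' \code{log pi_pos(mut) - log pi_pos(wt)}, which is exactly the quantity
#' the model's log-probability score estimates.
#'
#' @slot L alignment length.
#' @slot N number of sampled sequences (excluding the focus row).
#' @slot alpha Dirichlet concentration; lower is more conserved.
#' @slot gapRate per-cell gap probability in sampled rows, in [0, 0.9].
#' @slot nFounders,copiesPerFounder,copyMutationRate redundancy block;
#'   \code{nFounders * copiesPerFounder} must equal \code{N}.
#' @slot seed RNG seed.
#'
#' @export
setClass("FamilySpec", representation(
  L = "integer", N = "integer", alpha = "numeric", gapRate = "numeric",
  nFounders = "integer", copiesPerFounder = "integer",
  copyMutationRate = "numeric", seed = "integer"
))

setValidity("FamilySpec", function(object) {
  if (object@L < 1L || object@N < 1L) return("L and N must be >= 1")
  if (object@alpha <= 0) return("alpha must be > 0")
  if (object@gapRate < 0 || object@gapRate > 0.9)
    return("gapRate must lie in [0, 0.9]")
  if (object@copyMutationRate < 0 || object@copyMutationRate > 1)
    return("copyMutationRate must lie in [0, 1]")
  if (object@nFounders * object@copiesPerFounder != object@N)
    return("nFounders * copiesPerFounder must equal N")
  TRUE
})

#' GroundTruth: the generating profiles and closed-form variant effects
#'
#' @slot profiles L x 20 matrix of column distributions (rows sum to 1).
#' @slot wildType the consensus (profile argmax) focus sequence.
#' @slot alphabet the 20 canonical amino acids, in code order.
#'
#' @export
setClass("GroundTruth", representation(
  profiles = "matrix", wildType = "character", alphabet = "character"
))

#' @rdname FamilySpec-class
#' @param L,N,alpha,gapRate,nFounders,copiesPerFounder,copyMutationRate,seed
#'   see the class slots.
#' @export
familySpec <- function(L = 40L, N = 2000L, alpha = 0.1, gapRate = 0,
                       nFounders = N, copiesPerFounder = 1L,
                       copyMutationRate = 0, seed = 1L) {
  new("FamilySpec", L = as.integer(L), N = as.integer(N), alpha = alpha,
      gapRate = gapRate, nFounders = as.integer(nFounders),
      copiesPerFounder = as.integer(copiesPerFounder),
      copyMutationRate = copyMutationRate, seed = as.integer(seed))
}

#' Sample a synthetic protein family with known ground truth
#'
#' The focus row (the consensus sequence, id \code{"focus"}) is prepended
#' to the \code{N} sampled sequences, so the returned alignment has
#' \code{N + 1} records. Gap injection never touches the focus row.
#'
#' @param spec a \linkS4class{FamilySpec}.
#' @return list with elements \code{msa} (\linkS4class{ProteinMsa}) and
#'   \code{truth} (\linkS4class{GroundTruth}).
#' @export
sampleFamily <- function(spec) {
  validObject(spec)
  aa <- AA_ALPHABET_GAP[1:20]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec@seed)
  prof <- matrix(rgamma(spec@L * 20L, shape = spec@alpha), spec@L, 20L)
  # tiny concentrations can underflow a whole row to zero; redraw such
  # rows in log space (Marsaglia's boost: G_a = G_{a+1} * U^{1/a})
  for (l in which(rowSums(prof) == 0)) {
    lg <- log(rgamma(20L, shape = spec@alpha + 1)) +
      log(runif(20L)) / spec@alpha
    prof[l, ] <- exp(lg - max(lg))
  }
  prof <- prof / rowSums(prof)
  wtCodes <- apply(prof, 1L, which.max)
  founders <- vapply(seq_len(spec@L), function(l)
    sample.int(20L, spec@nFounders, replace = TRUE, prob = prof[l, ]),
    integer(spec@nFounders))
  founders <- matrix(founders, nrow = spec@nFounders)
  seqs <- founders[rep(seq_len(spec@nFounders),
                       each = spec@copiesPerFounder), , drop = FALSE]
  if (spec@copyMutationRate > 0) {
    flip <- matrix(runif(length(seqs)) < spec@copyMutationRate,
                   nrow = nrow(seqs))
    for (l in seq_len(spec@L)) {
      k <- sum(flip[, l])
      if (k > 0)
        seqs[flip[, l], l] <- sample.int(20L, k, replace = TRUE,
                                         prob = prof[l, ])
    }
  }
  chars <- matrix(aa[seqs], nrow = nrow(seqs))
  if (spec@gapRate > 0) {
    gaps <- matrix(runif(length(chars)) < spec@gapRate, nrow = nrow(chars))
    chars[gaps] <- "-"
  }
  wildType <- paste(aa[wtCodes], collapse = "")
  rows <- c(wildType, apply(chars, 1L, paste, collapse = ""))
  msa <- proteinMsa(rows, ids = c("focus", paste0("seq_", seq_len(spec@N))),
                    focusIndex = 1L)
  truth <- new("GroundTruth", profiles = prof, wildType = wildType,
               alphabet = aa)
  list(msa = msa, truth = truth)
}

#' True effect of a substitution under the generating profiles
#'
#' \code{log pi_pos(mut) - log pi_pos(wt)}, in nats; 0 for a wild-type
#' "substitution".
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param pos 1-based position.
#' @param mut mutant residue letter.
#' @return numeric effect (vectorised over \code{pos}/\code{mut}).
#' @export
trueEffect <- function(truth, pos, mut) {
  wtCode <- match(substring(truth@wildType, pos, pos), truth@alphabet)
  mutCode <- match(mut, truth@alphabet)
  log(truth@profiles[cbind(pos, mutCode)]) -
    log(truth@profiles[cbind(pos, wtCode)])
}

#' All single substitutions of the consensus with their true effects
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @return data.frame \code{variant, pos, wt, mut, effect} with exactly
#'   19 rows per position.
#' @export
allTrueEffects <- function(truth) {
  L <- nrow(truth@profiles)
  wt <- strsplit(truth@wildType, "")[[1]]
  rows <- do.call(rbind, lapply(seq_len(L), function(p) {
    muts <- setdiff(truth@alphabet, wt[p])
    data.frame(pos = p, wt = wt[p], mut = muts, stringsAsFactors = FALSE)
  }))
  rows$variant <- paste0(rows$wt, rows$pos, rows$mut)
  rows$effect <- trueEffect(truth, rows$pos, rows$mut)
  rows[, c("variant", "pos", "wt", "mut", "effect")]
}

#' Sample a balanced labelled variant set from the ground truth
#'
#' Variants are drawn uniformly over positions and substitutions and
#' labelled deleterious exactly when their true effect falls below
#' \code{effectThreshold}; rejection sampling fills the two classes to
#' balance. The returned z-proxy is the true effect standardised against
#' the full all-substitutions effect distribution, playing the role a
#' model z-score plays for real labelled sets.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param n number of labelled variants (split as evenly as possible).
#' @param effectThreshold label threshold in nats (default: the median
#'   effect over all substitutions).
#' @return data.frame \code{variant, pos, wt, mut, effect, z, label}.
#' @export
labelledVariants <- function(truth, n, effectThreshold = NULL) {
  if (n < 2L) stop("n must be >= 2")
  eff <- allTrueEffects(truth)
  if (is.null(effectThreshold))
    effectThreshold <- stats::median(eff$effect)
  del <- eff$effect < effectThreshold
  if (!any(del) || all(del))
    stop("effect threshold outside the effect range: cannot balance classes")
  mu <- mean(eff$effect)
  sdev <- sqrt(mean((eff$effect - mu)^2))
  nDel <- ceiling(n / 2); nBen <- n - nDel
  take <- function(pool, k) pool[sample.int(length(pool), k,
                                            replace = length(pool) < k)]
  idx <- c(take(which(del), nDel), take(which(!del), nBen))
  out <- eff[idx, , drop = FALSE]
  out$z <- (out$effect - mu) / sdev
  out$label <- ifelse(out$effect < effectThreshold, "deleterious", "benign")
  rownames(out) <- NULL
  out
}

#' Alignment fixture with columns at known gap fractions
#'
#' Builds a conserved alignment of \code{n} rows (focus row first,
#' gap-free) in which four designated columns carry gap fractions 0.00,
#' 0.30, 0.31 and 0.50 exactly, bracketing the 30\% filtering rule.
#'
#' @param n number of rows; must make the fractions exact (default 100).
#' @param L alignment width (>= 8).
#' @return list with \code{msa} and \code{columns} (data.frame
#'   \code{col, gap_fraction}).
#' @export
gapColumnFixture <- function(n = 100L, L = 10L) {
  fracs <- c(0, 0.30, 0.31, 0.50)
  counts <- fracs * n
  if (any(counts != round(counts)))
    stop("n must make the designated gap fractions exact")
  cols <- c(2L, 4L, 6L, 8L)
  base <- strsplit(paste(rep("ACDEFGHIKLMNPQRSTVWY", 3), collapse = ""),
                   "")[[1]][seq_len(L)]
  m <- matrix(rep(base, each = n), nrow = n)
  for (i in seq_along(cols)) {
    k <- counts[i]
    if (k > 0) m[1L + seq_len(k), cols[i]] <- "-"   # never the focus row
  }
  msa <- proteinMsa(apply(m, 1L, paste, collapse = ""),
                    ids = c("focus", paste0("seq_", seq_len(n - 1L))))
  list(msa = msa, columns = data.frame(col = cols, gap_fraction = fracs))
}

#' Write a synthetic family and its ground truth to disk
#'
#' The alignment goes to FASTA; the profiles to a tab-separated table
#' (position, residue, probability); the variant effects to a
#' tab-separated table of all substitutions.
#'
#' @param family list from \code{\link{sampleFamily}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeFamily <- function(family, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "family.fasta")
  writeLines(paste0(">", family$msa@ids, "\n", family$msa@rows), fasta)
  prof <- family$truth@profiles
  profTab <- data.frame(
    position = rep(seq_len(nrow(prof)), each = ncol(prof)),
    residue = rep(family$truth@alphabet, nrow(prof)),
    probability = as.vector(t(prof))
  )
  profPath <- file.path(dir, "profiles.tsv")
  write.table(profTab, profPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  effPath <- file.path(dir, "true_effects.tsv")
  write.table(allTrueEffects(family$truth), effPath, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta, profiles = profPath, effects = effPath))
}
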