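## Dataset curation, scaffold-stratified size-nested splits,
## similarity-stratified fine-tuning sets, and the synthetic fixture
## generator that stands in for external compound databases in tests.

#' Create a curation policy
#'
#' @param allowed_atoms Element symbols a molecule may contain (aromatic
#'   lowercase forms are covered implicitly).
#' @param min_tokens,max_tokens Token-count bounds on the canonical SMILES;
#'   strings shorter than `min_tokens` or longer than `max_tokens` are
#'   rejected.
#' @param strip_salts Keep only the largest covalent fragment.
#' @param strip_stereo Remove stereochemistry annotations.
#' @return A [CurationPolicy-class].
#' @export
curationPolicy <- function(allowed_atoms = c("C", "O", "N", "S", "P", "F",
                                             "Cl", "Br", "I"),
                           min_tokens = 6L, max_tokens = 150L,
                           strip_salts = TRUE, strip_stereo = TRUE) {
  new("CurationPolicy", allowed_atoms = allowed_atoms,
      min_tokens = as.integer(min_tokens),
      max_tokens = as.integer(max_tokens),
      strip_salts = as.logical(strip_salts),
      strip_stereo = as.logical(strip_stereo))
}

#' Curate raw SMILES
#'
#' Standard preprocessing for training corpora: desalt (keep the largest
#' covalent fragment), neutralize charges, strip stereochemistry, sanitize,
#' drop molecules containing atoms outside the allowed set, drop canonical
#' SMILES outside the token-length bounds, and deduplicate by canonical
#' form.  Every rejection is logged with a machine-readable reason code
#' (`PARSE`, `ATOM`, `LENGTH`, `DUP`).  Each surviving molecule gets one
#' randomized SMILES attached (the training representation).
#'
#' @param raw Character vector of SMILES lines.
#' @param policy A [CurationPolicy-class].
#' @param seed Integer seed for the attached randomized SMILES.
#' @return A [CuratedSmiles-class].
#' @export
curateSmiles <- function(raw, policy = curationPolicy(), seed = 1L) {
  stopifnot(is.character(raw), length(raw) >= 1L,
            is(policy, "CurationPolicy"))
  validObject(policy)
  res <- rdkitBridge("curate", list(smiles = I(raw)))
  valid <- unlist(res$valid)
  reason <- rep(NA_character_, length(raw))
  reason[!valid] <- "PARSE"
  canonical <- rep(NA_character_, length(raw))
  canonical[valid] <- unlist(res$canonical[valid])
  for (i in which(valid)) {
    elems <- unlist(res$elements[[i]])
    if (!all(elems %in% policy@allowed_atoms)) {
      reason[i] <- "ATOM"
      next
    }
    ntok <- tryCatch(length(.tokenizeOne(canonical[i])),
                     error = function(e) NA_integer_)
    if (is.na(ntok)) {
      reason[i] <- "PARSE"
    } else if (ntok < policy@min_tokens || ntok > policy@max_tokens) {
      reason[i] <- "LENGTH"
    }
  }
  keep <- is.na(reason)
  dup <- keep & duplicated(canonical)
  reason[dup] <- "DUP"
  keep <- is.na(reason)
  records <- data.frame(id = paste0("M", seq_len(sum(keep))),
                        input_smiles = raw[keep],
                        canonical_smiles = canonical[keep],
                        stringsAsFactors = FALSE)
  if (nrow(records)) {
    records$randomized_smiles <-
      vapply(randomizeSmiles(records$canonical_smiles, 1L, seed = seed),
             `[`, character(1), 1L)
  } else {
    records$randomized_smiles <- character(0)
  }
  rejections <- data.frame(input_smiles = raw[!keep],
                           reason = reason[!keep],
                           stringsAsFactors = FALSE)
  rownames(records) <- rownames(rejections) <- NULL
  new("CuratedSmiles", records = records, rejections = rejections)
}

#' @describeIn curateSmiles The table of surviving molecules.
#' @param x A [CuratedSmiles-class].
#' @export
curatedRecords <- function(x) {
  stopifnot(is(x, "CuratedSmiles"))
  x@records
}

#' @describeIn curateSmiles The rejection log with reason codes.
#' @export
rejectionLog <- function(x) {
  stopifnot(is(x, "CuratedSmiles"))
  x@rejections
}

## Spectral clustering of scaffold classes.  Affinity between classes is
## the Tanimoto similarity of Morgan fingerprints computed on the generic
## scaffolds (the empty scaffold of acyclic molecules forms its own class,
## similar only to itself).  Returns a cluster label per class.
.spectralClusterScaffolds <- function(scaffolds, k) {
  n <- length(scaffolds)
  if (k >= n) return(seq_len(n))
  A <- matrix(0, n, n)
  nonempty <- nzchar(scaffolds)
  if (sum(nonempty) > 1L) {
    A[nonempty, nonempty] <- tanimotoMatrix(scaffolds[nonempty])
  } else if (sum(nonempty) == 1L) {
    A[nonempty, nonempty] <- 1
  }
  diag(A) <- 1
  d <- rowSums(A)
  Dm <- 1 / sqrt(d)
  Lsym <- t(A * Dm) * Dm        # D^-1/2 A D^-1/2
  eig <- eigen(Lsym, symmetric = TRUE)
  U <- eig$vectors[, seq_len(k), drop = FALSE]
  norms <- sqrt(rowSums(U^2))
  norms[norms == 0] <- 1
  U <- U / norms
  stats::kmeans(U, centers = k, nstart = 10L, iter.max = 100L)$cluster
}

## Largest-remainder allocation of `size` draws across clusters with
## target proportions prop, capped element-wise by `limit` (used to keep
## nested subsets monotone per cluster).
.stratifiedAllocation <- function(size, prop, limit) {
  target <- size * prop
  base <- pmin(floor(target), limit)
  rem <- size - sum(base)
  if (rem > 0) {
    frac <- target - floor(target)
    ord <- order(-frac, seq_along(prop))
    for (i in ord) {
      if (rem == 0) break
      if (base[i] < limit[i]) {
        base[i] <- base[i] + 1L
        rem <- rem - 1L
      }
    }
    ## if still short (caps bound), fill wherever room remains
    if (rem > 0) {
      for (i in order(-limit + base)) {
        while (rem > 0 && base[i] < limit[i]) {
          base[i] <- base[i] + 1L
          rem <- rem - 1L
        }
      }
    }
  }
  as.integer(base)
}

#' Scaffold-stratified, size-nested dataset splits
#'
#' Clusters molecules by spectral clustering on their generic Bemis-Murcko
#' scaffolds, then draws size-nested subsets by stratified sampling over
#' the cluster assignment (every smaller subset is contained in each larger
#' one, and cluster proportions are preserved at every size within
#' rounding).  Each subset is split 90/10 into training and validation;
#' a disjoint, cluster-stratified test set is drawn from the remaining
#' pool.
#'
#' @param smiles Character vector of curated canonical SMILES, or a
#'   [CuratedSmiles-class].
#' @param sizes Ascending subset sizes (full-scale runs use
#'   1000/2500/5000/7500/10000; fixtures use smaller values).
#' @param test_size Size of the held-out test set.
#' @param n_clusters Requested number of scaffold clusters; reduced with a
#'   warning when there are fewer scaffold classes.
#' @param train_fraction Training share of each subset.
#' @param seed Integer seed.
#' @return A [SplitPlan-class].
#' @export
scaffoldClusterSplit <- function(smiles, sizes, test_size = 0L,
                                 n_clusters = 10L, train_fraction = 0.9,
                                 seed = 1L) {
  if (is(smiles, "CuratedSmiles")) smiles <- smiles@records$canonical_smiles
  stopifnot(is.character(smiles), length(sizes) >= 1L,
            !is.unsorted(sizes), train_fraction > 0, train_fraction < 1)
  sizes <- as.integer(sizes)
  n <- length(smiles)
  if (max(sizes) + test_size > n) {
    stop("need at least max(sizes) + test_size = ", max(sizes) + test_size,
         " molecules, got ", n, call. = FALSE)
  }
  scaf <- bemisMurckoScaffold(smiles, generic = TRUE)
  classes <- unique(scaf)
  k <- n_clusters
  if (k > length(classes)) {
    warning("only ", length(classes), " scaffold classes; reducing ",
            "cluster count from ", n_clusters)
    k <- length(classes)
  }
  withr::with_seed(seed, {
    class_cluster <- .spectralClusterScaffolds(classes, k)
    clusters <- class_cluster[match(scaf, classes)]
    prop <- as.numeric(table(factor(clusters, levels = seq_len(k)))) / n
    ## fixed random order within each cluster; nested subsets take prefixes
    by_cluster <- lapply(seq_len(k), function(cl) {
      idx <- which(clusters == cl)
      idx[sample.int(length(idx))]
    })
    limit <- lengths(by_cluster)
    subsets <- vector("list", length(sizes))
    alloc_prev <- rep(0L, k)
    for (s in rev(seq_along(sizes))) {   # allocate largest first
      lim <- if (s == length(sizes)) limit else alloc_prev
      alloc <- .stratifiedAllocation(sizes[s], prop, lim)
      subsets[[s]] <- sort(unlist(lapply(seq_len(k), function(cl)
        utils::head(by_cluster[[cl]], alloc[cl]))))
      alloc_prev <- alloc
    }
    names(subsets) <- paste0("n", sizes)
    train <- val <- vector("list", length(sizes))
    for (s in seq_along(sizes)) {
      idx <- subsets[[s]]
      n_val <- max(1L, round((1 - train_fraction) * length(idx)))
      v <- sort(idx[sample.int(length(idx), n_val)])
      val[[s]] <- v
      train[[s]] <- setdiff(idx, v)
    }
    names(train) <- names(val) <- names(subsets)
    test <- integer(0)
    if (test_size > 0L) {
      pool_by_cluster <- lapply(seq_len(k), function(cl)
        setdiff(by_cluster[[cl]], subsets[[length(sizes)]]))
      pool_n <- sum(lengths(pool_by_cluster))
      if (test_size > pool_n) {
        stop("test_size exceeds the ", pool_n,
             " molecules left outside the largest subset", call. = FALSE)
      }
      pp <- lengths(pool_by_cluster) / pool_n
      alloc <- .stratifiedAllocation(test_size, pp,
                                     lengths(pool_by_cluster))
      test <- sort(unlist(lapply(seq_len(k), function(cl)
        utils::head(pool_by_cluster[[cl]], alloc[cl]))))
    }
    new("SplitPlan", sizes = sizes, subsets = subsets, train = train,
        val = val, test = as.integer(test), clusters = as.integer(clusters))
  })
}

#' @describeIn scaffoldClusterSplit Record indices of one subset of a plan.
#' @param plan A [SplitPlan-class].
#' @param size Subset size to extract.
#' @param part `"all"`, `"train"` or `"val"`.
#' @export
splitIndices <- function(plan, size, part = c("all", "train", "val")) {
  stopifnot(is(plan, "SplitPlan"))
  part <- match.arg(part)
  key <- paste0("n", as.integer(size))
  src <- switch(part, all = plan@subsets, train = plan@train,
                val = plan@val)
  if (!key %in% names(src)) {
    stop("no subset of size ", size, " in this plan", call. = FALSE)
  }
  src[[key]]
}

#' Similarity-stratified fine-tuning sets
#'
#' Selects fine-tuning molecules by pairwise ECFP Tanimoto similarity
#' (radius 2, 1024 bits).  Mode `"high"` performs agglomerative clustering
#' into parent clusters and subclusters, then searches clusters larger than
#' the target size for a subset whose pairwise similarity is at least
#' `high_threshold`.  Mode `"low"` runs greedy leader selection so that all
#' pairwise similarities are at most `low_threshold`.  Both modes return
#' exactly `size` molecules or raise an error naming the achievable
#' maximum.
#'
#' @param smiles Character vector of valid SMILES.
#' @param size Number of molecules to select (typical fine-tuning sizes are 10 and 100).
#' @param mode `"high"` or `"low"`.
#' @param high_threshold,low_threshold Pairwise similarity bounds.
#' @param n_parent,n_sub Agglomerative parent/subcluster counts (the 20/40
#'   defaults shrink proportionally below 200 molecules).
#' @param seed Integer seed.
#' @return Character vector of `size` selected SMILES.
#' @export
similaritySets <- function(smiles, size, mode = c("high", "low"),
                           high_threshold = 0.8, low_threshold = 0.4,
                           n_parent = 20L, n_sub = 40L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(is.character(smiles), size >= 2L)
  n <- length(smiles)
  if (size > n) {
    stop("requested ", size, " molecules but only ", n, " available",
         call. = FALSE)
  }
  sim <- tanimotoMatrix(smiles)
  withr::with_seed(seed, {
    if (mode == "low") {
      ord <- sample.int(n)
      kept <- integer(0)
      for (i in ord) {
        if (all(sim[i, kept] <= low_threshold)) kept <- c(kept, i)
        if (length(kept) == size) break
      }
      if (length(kept) < size) {
        stop("cannot select ", size, " molecules with pairwise similarity <= ",
             low_threshold, "; achievable maximum here: ", length(kept),
             call. = FALSE)
      }
      return(smiles[kept])
    }
    ## high-similarity mode
    if (n < 200L) {
      n_parent <- max(2L, as.integer(floor(n_parent * n / 200)))
      n_sub <- min(n - 1L, 2L * n_parent)
    }
    hc <- stats::hclust(stats::as.dist(1 - sim), method = "complete")
    memberships <- c(split(seq_len(n), stats::cutree(hc, k = n_sub)),
                     split(seq_len(n), stats::cutree(hc, k = n_parent)))
    memberships <- memberships[order(-lengths(memberships))]
    best <- integer(0)
    for (mem in memberships) {
      if (length(mem) < size) next
      ## greedy growth from each seed member
      for (s0 in mem[sample.int(length(mem))]) {
        sel <- s0
        for (cand in mem[sample.int(length(mem))]) {
          if (cand %in% sel) next
          if (all(sim[cand, sel] >= high_threshold)) sel <- c(sel, cand)
          if (length(sel) == size) break
        }
        if (length(sel) > length(best)) best <- sel
        if (length(best) >= size) break
      }
      if (length(best) >= size) break
    }
    if (length(best) < size) {
      stop("cannot select ", size, " molecules with pairwise similarity >= ",
           high_threshold, "; achievable maximum here: ", length(best),
           call. = FALSE)
    }
    smiles[best]
  })
}

## ---- synthetic fixture generator ------------------------------------

## Ring cores with one substitution slot.
.FIXTURE_CORES <- c(
  "c1ccc(%s)cc1",            # benzene
  "c1ccc(%s)nc1",            # pyridine
  "c1ncc(%s)cn1",            # pyrimidine
  "c1cc(%s)sc1",             # thiophene
  "c1cc(%s)oc1",             # furan
  "c1cc(%s)[nH]c1",          # pyrrole
  "c1ccc2cc(%s)ccc2c1",      # naphthalene
  "C1CCC(%s)CC1",            # cyclohexane
  "C1CC(%s)CC1",             # cyclopentane
  "C1CCN(%s)CC1",            # piperidine (N-linked)
  "C1CN(%s)CCO1",            # morpholine (N-linked)
  "C1CN(%s)CCN1C",           # N-methylpiperazine
  "C1CC(%s)CO1",             # tetrahydrofuran
  "c1csc(-c2ccc(%s)cc2)c1",  # phenylthiophene (biaryl)
  "O=C1CCCN1%s"              # pyrrolidinone (N-linked)
)

## Linkers between core and functional group.
.FIXTURE_LINKERS <- c("", "C", "CC", "CCC")

## Terminal substituents; together they cover every functional group in
## the bundled SMARTS library.
.FIXTURE_GROUPS <- c(
  "C(=O)O",            # carboxylic acid
  "C(=O)OC",           # methyl ester
  "C(=O)NC",           # N-methyl amide
  "C(=O)N",            # primary amide
  "N",                 # primary amine
  "O",                 # hydroxyl
  "OC",                # methyl ether
  "C#N",               # nitrile
  "[N+](=O)[O-]",      # nitro
  "F", "Cl", "Br", "I",# halogens
  "C(C)=O",            # methyl ketone
  "C=O",               # aldehyde
  "S(=O)(=O)NC",       # sulfonamide
  "S(=O)(=O)N",        # primary sulfonamide
  "SC",                # thioether
  "c3ccccc3",          # phenyl
  "c3ccncc3",          # pyridyl
  "C3CCCCC3",          # cyclohexyl
  "N3CCOCC3"           # morpholino
)

## Analog series: a large fixed frame with one small variable site, so the
## members share most ECFP substructures (pairwise Tanimoto >= 0.8).  Used
## by tests needing feasible high-similarity fine-tuning sets.
.FIXTURE_ANALOG_FRAMES <- c(
  "CC(=O)Nc1ccc(OCC(=O)Nc2ccc(cc2)CN2CCN(CC2)C(=O)c2ccc(cc2)S(=O)(=O)N2CCCC2)cc1%s",
  "O=C(Nc1ccc(cc1)S(=O)(=O)N1CCCCC1)c1ccc(OCCN2CCOCC2)cc1NC(=O)c1ccc(C)cc1%s"
)

.FIXTURE_ANALOG_SITES <- c("F", "Cl", "Br", "I", "C", "O", "N", "OC",
                           "CC", "SC", "C#N", "OCC", "CCC", "C(C)C",
                           "C(=O)O", "C(=O)N")

## Full deterministic design space, coverage entries first.
.fixtureSpace <- function() {
  analogs <- as.vector(vapply(.FIXTURE_ANALOG_FRAMES, function(fr)
    vapply(.FIXTURE_ANALOG_SITES, function(s) sprintf(fr, s), character(1)),
    character(length(.FIXTURE_ANALOG_SITES))))
  coverage <- vapply(.FIXTURE_GROUPS, function(g)
    sprintf("c1ccc(%s)cc1", g), character(1))
  ## symmetric core/substituent pairs whose product duplicates another
  ## grid entry (e.g. cyclohexane + phenyl == benzene + cyclohexyl)
  skip <- list(c("C1CCC(%s)CC1", "c3ccccc3"),
               c("C1CN(%s)CCO1", "c3ccccc3"),
               c("C1CN(%s)CCO1", "C3CCCCC3"))
  grid <- character(0)
  for (core in .FIXTURE_CORES) {
    for (link in .FIXTURE_LINKERS) {
      for (grp in .FIXTURE_GROUPS) {
        if (any(vapply(skip, function(s)
          identical(s, c(core, grp)), logical(1)))) next
        grid <- c(grid, sprintf(core, paste0(link, grp)))
      }
    }
  }
  grid <- setdiff(grid, coverage)
  list(head = unname(c(coverage, analogs)), tail = unname(grid))
}

#' Generate a synthetic drug-like SMILES library
#'
#' Deterministically generates `n` valid, curation-passing, drug-like
#' SMILES by combinatorial decoration of a built-in design space: ring
#' cores (aromatic and aliphatic, mono- and bicyclic) crossed with alkyl /
#' ether linkers and a substituent panel covering every functional group in
#' the bundled SMARTS library, plus two large analog series with a single
#' variable site (guaranteeing feasible high-similarity subsets).  The
#' coverage and analog entries always precede a seed-shuffled sample of the
#' remaining grid, so any `n` of at least 60 covers all functional groups;
#' 500 molecules span well over 20 distinct Bemis-Murcko scaffolds.
#'
#' @param n Number of SMILES to generate.
#' @param seed Integer seed; the same seed reproduces the identical list.
#' @return Character vector of `n` distinct SMILES.
#' @export
generateFixtureLibrary <- function(n, seed = 42L) {
  stopifnot(n >= 1L)
  space <- .fixtureSpace()
  total <- length(space$head) + length(space$tail)
  if (n > total) {
    stop("the fixture design space holds at most ", total, " molecules",
         call. = FALSE)
  }
  withr::with_seed(seed, {
    head_shuffled <- space$head[sample.int(length(space$head))]
    tail_shuffled <- space$tail[sample.int(length(space$tail))]
  })
  utils::head(c(head_shuffled, tail_shuffled), n)
}
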