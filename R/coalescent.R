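# Neutral infinite-sites coalescent with recombination, reference
# ascertainment and spectrum comparison.

#' Effective population size from Watterson's per-bp theta
#'
#' Solves `theta_W = 4 * Ne * mu` for Ne, reported truncated to an integer.
#'
#' @param theta_w_per_bp population-scaled per-bp mutation rate.
#' @param mu per-bp per-generation mutation rate (default 7e-9).
#' @return integer Ne.
#' @export
#' @examples
#' estimate_ne(8.3e-4)  # 29642
estimate_ne <- function(theta_w_per_bp, mu = 7e-9) {
  if (!is.numeric(theta_w_per_bp) || theta_w_per_bp <= 0 || mu <= 0) {
    stop("theta and mu must be positive", call. = FALSE)
  }
  trunc(theta_w_per_bp / (4 * mu))
}

#' Watterson's harmonic correction a_n
#' @param n sample size (number of chromosomes).
#' @return `sum(1 / (1:(n-1)))`.
#' @export
watterson_a <- function(n) {
  stopifnot(n >= 2)
  sum(1 / seq_len(n - 1L))
}

#' Per-locus theta from an observed number of events
#'
#' Watterson's estimator: `theta = S / a_n`.
#'
#' @param S observed segregating events.
#' @param n_chrom sample size.
#' @return theta per locus.
#' @export
estimate_theta_locus <- function(S, n_chrom) {
  stopifnot(S >= 0, n_chrom >= 2)
  S / watterson_a(n_chrom)
}

#' Population-genetic simulation parameters
#'
#' Defaults describe a selfing crop panel treated as haploid chromosomes:
#' sample size 42 (41 test lines plus the designated reference as row 1),
#' per-locus recombination rate 21.54 for a ~14 kb locus (the average size
#' of a called CGH segment), mutation rate 7e-9 per bp per generation.
#'
#' @param theta_locus population-scaled per-locus mutation rate.
#' @param n_chrom sampled chromosomes, including the reference.
#' @param rho_locus population-scaled per-locus recombination rate.
#' @param n_loci number of independent loci.
#' @param locus_bp locus size in bp (bookkeeping only; loci are simulated
#'   on a unit interval).
#' @param mu per-bp mutation rate.
#' @param seed random seed.
#' @return list of class `popgen_params`.
#' @export
popgen_params <- function(theta_locus = 1, n_chrom = 42L, rho_locus = 21.54,
                          n_loci = 100L, locus_bp = 14000, mu = 7e-9,
                          seed = 1L) {
  stopifnot(theta_locus >= 0, rho_locus >= 0, n_chrom >= 2, n_loci >= 1,
            locus_bp > 0, mu > 0)
  structure(list(theta_locus = theta_locus, n_chrom = as.integer(n_chrom),
                 rho_locus = rho_locus, n_loci = as.integer(n_loci),
                 locus_bp = locus_bp, mu = mu, seed = as.integer(seed)),
            class = "popgen_params")
}

# One locus without recombination: plain Kingman coalescent.
# Returns list(weights, leaves): branch weights (coalescent time x unit
# locus length) and the leaf set under each branch.
sim_locus_kingman <- function(n) {
  active <- as.list(seq_len(n))
  birth <- rep(0, n)
  t_now <- 0
  w <- numeric(2L * (n - 1L))
  leaves <- vector("list", 2L * (n - 1L))
  nb <- 0L
  k <- n
  while (k > 1L) {
    t_now <- t_now + stats::rexp(1, k * (k - 1L) / 2)
    pair <- sample.int(k, 2L)
    i <- pair[1]; j <- pair[2]
    for (idx in c(i, j)) {
      nb <- nb + 1L
      w[nb] <- t_now - birth[idx]
      leaves[[nb]] <- active[[idx]]
    }
    merged <- c(active[[i]], active[[j]])
    active[[i]] <- merged
    birth[i] <- t_now
    active[[j]] <- NULL
    birth <- birth[-j]
    k <- k - 1L
  }
  list(w = w[seq_len(nb)], leaves = leaves[seq_len(nb)])
}

# One locus with recombination: ancestral recombination graph on the unit
# interval. Lineages carry lists of ancestral segments, each segment an
# interval plus the set of sampled chromosomes descending from it. A
# segment whose leaf set reaches the full sample has found its MRCA and is
# no longer tracked. Branch "area" (duration x segment length) accumulates
# per lineage lifetime and carries the leaf set for mutation placement.
sim_locus_arg <- function(n, rho) {
  # Lineages live in slots 1..k of a growable list; spans are cached per
  # lineage and deletions swap with the last slot. A lineage is
  # list(birth, segs, sl, sr) with segs = list of list(l, r, lv).
  new_seg <- function(l, r, lv) list(l = l, r = r, lv = lv)
  cap <- 4L * n
  lineages <- vector("list", cap)
  spans <- numeric(cap)
  for (i in seq_len(n)) {
    lineages[[i]] <- list(birth = 0, segs = list(new_seg(0, 1, i)),
                          sl = 0, sr = 1)
    spans[i] <- 1
  }
  k <- n
  t_now <- 0
  w <- numeric(256L)
  leaves <- vector("list", 256L)
  nb <- 0L
  emit <- function(lin) {
    dur <- t_now - lin$birth
    if (dur <= 0) return(invisible())
    for (s in lin$segs) {
      nb <<- nb + 1L
      if (nb > length(w)) {
        length(w) <<- 2L * length(w)
        length(leaves) <<- 2L * length(leaves)
      }
      w[nb] <<- dur * (s$r - s$l)
      leaves[[nb]] <<- s$lv
    }
    invisible()
  }
  make_lineage <- function(segs) {
    ls <- vapply(segs, `[[`, numeric(1), "l")
    rs <- vapply(segs, `[[`, numeric(1), "r")
    list(birth = t_now, segs = segs, sl = min(ls), sr = max(rs))
  }
  put <- function(idx, lin) {
    if (idx > cap) {
      cap <<- 2L * cap
      length(lineages) <<- cap
      length(spans) <<- cap
    }
    lineages[[idx]] <<- lin
    spans[idx] <<- lin$sr - lin$sl
  }
  drop_slot <- function(idx) {
    if (idx != k) {
      lineages[[idx]] <<- lineages[[k]]
      spans[idx] <<- spans[k]
    }
    k <<- k - 1L
  }
  while (k > 1L) {
    rate_c <- k * (k - 1L) / 2
    rate_r <- rho / 2 * sum(spans[seq_len(k)])
    t_now <- t_now + stats::rexp(1, rate_c + rate_r)
    if (stats::runif(1) * (rate_c + rate_r) < rate_r) {
      # Recombination: split one lineage at a uniform point of its span.
      li <- sample.int(k, 1L, prob = spans[seq_len(k)])
      lin <- lineages[[li]]
      bp <- stats::runif(1, lin$sl, lin$sr)
      left <- list(); right <- list()
      for (s in lin$segs) {
        if (s$r <= bp) left[[length(left) + 1L]] <- s
        else if (s$l >= bp) right[[length(right) + 1L]] <- s
        else {
          left[[length(left) + 1L]] <- new_seg(s$l, bp, s$lv)
          right[[length(right) + 1L]] <- new_seg(bp, s$r, s$lv)
        }
      }
      emit(lin)
      put(li, make_lineage(left))
      put(k + 1L, make_lineage(right))
      k <- k + 1L
    } else {
      # Coalescence: merge two lineages; overlapping ancestral intervals
      # union their leaf sets, full-sample intervals are retired.
      pair <- sample.int(k, 2L)
      a <- lineages[[pair[1]]]; b <- lineages[[pair[2]]]
      emit(a); emit(b)
      segs <- c(a$segs, b$segs)
      cuts <- sort(unique(c(vapply(segs, `[[`, numeric(1), "l"),
                            vapply(segs, `[[`, numeric(1), "r"))))
      merged <- list()
      for (ii in seq_len(length(cuts) - 1L)) {
        l <- cuts[ii]; r <- cuts[ii + 1L]
        lv <- integer(0)
        for (s in segs) {
          if (s$l <= l && s$r >= r) lv <- c(lv, s$lv)
        }
        lv <- unique(lv)
        if (length(lv) == 0L || length(lv) == n) next
        last <- if (length(merged)) merged[[length(merged)]] else NULL
        if (!is.null(last) && last$r == l && length(last$lv) == length(lv) &&
            setequal(last$lv, lv)) {
          merged[[length(merged)]]$r <- r
        } else {
          merged[[length(merged) + 1L]] <- new_seg(l, r, lv)
        }
      }
      i1 <- min(pair); i2 <- max(pair)
      drop_slot(i2)
      if (length(merged)) {
        put(i1, make_lineage(merged))
      } else {
        drop_slot(i1)
      }
    }
  }
  if (k == 1L) emit(lineages[[1]])
  list(w = w[seq_len(nb)], leaves = leaves[seq_len(nb)])
}

# Place infinite-sites mutations on branch areas and build the 0/1 matrix.
mutate_locus <- function(branches, n, theta) {
  W <- sum(branches$w)
  S <- stats::rpois(1, theta / 2 * W)
  m <- matrix(0L, n, S)
  if (S > 0) {
    picks <- sample.int(length(branches$w), S, replace = TRUE,
                        prob = branches$w)
    for (s in seq_len(S)) {
      m[branches$leaves[[picks[s]]], s] <- 1L
    }
    m <- m[, order(stats::runif(S)), drop = FALSE]
  }
  m
}

#' Simulate independent neutral loci
#'
#' Standard neutral coalescent with recombination on independent unit-length
#' loci: per-locus genealogies (ancestral recombination graph when
#' `rho_locus > 0`), Poisson(`theta/2` x total branch area) mutations placed
#' uniformly on branches, infinite sites. Row 1 of every haplotype matrix is
#' the designated reference chromosome; `0` is the ancestral state
#' (presence), `1` the derived state (absence).
#'
#' @param params a [popgen_params()].
#' @return list of `n_loci` binary matrices (`n_chrom` rows; one column per
#'   segregating site).
#' @export
simulate_neutral <- function(params = popgen_params()) {
  stopifnot(inherits(params, "popgen_params"))
  set.seed(params$seed)
  n <- params$n_chrom
  lapply(seq_len(params$n_loci), function(i) {
    branches <- if (params$rho_locus == 0) {
      sim_locus_kingman(n)
    } else {
      sim_locus_arg(n, params$rho_locus)
    }
    mutate_locus(branches, n, params$theta_locus)
  })
}

#' Unascertained site frequency spectrum of simulated loci
#'
#' @param haplotypes list of binary matrices from [simulate_neutral()].
#' @return `sv_spectrum` over derived-allele counts 1..n-1.
#' @export
sfs_unascertained <- function(haplotypes) {
  n <- nrow(haplotypes[[1]])
  counts <- integer(n - 1L)
  for (m in haplotypes) {
    if (ncol(m)) counts <- counts + tabulate(colSums(m), nbins = n - 1L)
  }
  structure(counts, n_test = n - 1L, label = "simulated-unascertained",
            class = "sv_spectrum")
}

#' Reference-based ascertainment of simulated loci
#'
#' Designates row 1 as the reference chromosome: every site at which the
#' reference carries the derived state is discarded; for the remaining
#' sites the carrier count k is the number of derived alleles among the
#' other n-1 chromosomes. Mirrors an all-by-one array/read-depth design in
#' which variants are only visible as differences from the reference.
#'
#' @param haplotypes list of binary matrices from [simulate_neutral()].
#' @return `sv_spectrum` over k = 1..n-1 with attributes `n_kept` and
#'   `n_discarded` (kept + discarded = total segregating sites).
#' @export
ascertain_reference <- function(haplotypes) {
  stopifnot(length(haplotypes) >= 1L, nrow(haplotypes[[1]]) >= 2L)
  n <- nrow(haplotypes[[1]])
  counts <- integer(n - 1L)
  kept <- 0L; discarded <- 0L
  for (m in haplotypes) {
    if (!ncol(m)) next
    ref_derived <- m[1, ] == 1L
    discarded <- discarded + sum(ref_derived)
    keep <- m[, !ref_derived, drop = FALSE]
    if (ncol(keep)) {
      k <- colSums(keep[-1, , drop = FALSE])
      kept <- kept + ncol(keep)
      counts <- counts + tabulate(k, nbins = n - 1L)
    }
  }
  structure(counts, n_test = n - 1L, label = "simulated-ascertained",
            n_kept = kept, n_discarded = discarded, class = "sv_spectrum")
}

#' Compare an empirical spectrum with a simulated one
#'
#' Both spectra are normalized to proportions over the shared k range.
#' Reports per-class proportion differences, the singleton excess
#' (`empirical[1] - simulated[1]`, in proportion units) and a chi-square
#' distance with a resampling p-value (empirical-sized multinomial draws
#' from the simulated proportions).
#'
#' @param empirical,simulated `sv_spectrum` objects on the same k range.
#' @param n_resample resampling replicates for the p-value.
#' @param seed random seed.
#' @return object of class `spectrum_comparison`: list with `k`,
#'   `p_empirical`, `p_simulated`, `diff`, `singleton_excess`, `chisq`,
#'   `p_value`.
#' @export
compare_spectra <- function(empirical, simulated, n_resample = 10000L,
                            seed = 1L) {
  ne <- sum(empirical); ns <- sum(simulated)
  if (ne == 0L || ns == 0L) stop("empty spectrum", call. = FALSE)
  if (length(empirical) != length(simulated)) {
    stop("spectra must share the same k range", call. = FALSE)
  }
  pe <- as.integer(empirical) / ne
  ps <- as.integer(simulated) / ns
  keep <- ps > 0
  chisq_stat <- function(obs_counts) {
    exp_counts <- ne * ps[keep]
    sum((obs_counts[keep] - exp_counts)^2 / exp_counts)
  }
  obs <- chisq_stat(as.integer(empirical))
  set.seed(seed)
  draws <- stats::rmultinom(n_resample, ne, ps)
  null_stats <- apply(draws, 2, chisq_stat)
  structure(list(
    k = seq_along(empirical),
    p_empirical = pe, p_simulated = ps, diff = pe - ps,
    singleton_excess = pe[1] - ps[1],
    chisq = obs,
    p_value = (sum(null_stats >= obs) + 1) / (n_resample + 1)
  ), class = "spectrum_comparison")
}

#' @export
print.spectrum_comparison <- function(x, ...) {
  cat("Spectrum comparison (empirical vs simulated neutral)\n")
  cat(sprintf("  singleton excess: %+0.4f (proportion units)\n",
              x$singleton_excess))
  cat(sprintf("  chi-square distance: %.2f, resampling p = %.4g\n",
              x$chisq, x$p_value))
  invisible(x)
}

#' Write simulated haplotypes in ms-style text
#'
#' One `//` block per locus with `segsites:` and `positions:` lines and one
#' 0/1 row per sampled chromosome, for cross-checking against external
#' coalescent tools.
#'
#' @param haplotypes list of binary matrices.
#' @param path output file.
#' @param positions optional list of per-locus position vectors; defaults
#'   to uniform draws being omitted (equally spaced placeholders).
#' @export
write_ms <- function(haplotypes, path, positions = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("ms %d %d", nrow(haplotypes[[1]]), length(haplotypes)),
             con)
  writeLines("", con)
  for (i in seq_along(haplotypes)) {
    m <- haplotypes[[i]]
    writeLines("//", con)
    writeLines(sprintf("segsites: %d", ncol(m)), con)
    if (ncol(m)) {
      pos <- if (!is.null(positions)) positions[[i]] else
        seq_len(ncol(m)) / (ncol(m) + 1)
      writeLines(paste("positions:", paste(sprintf("%.5f", pos),
                                           collapse = " ")), con)
      writeLines(apply(m, 1, paste, collapse = ""), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Read ms-style haplotype text
#' @param path file written by [write_ms()] (or ms itself).
#' @return list of binary matrices.
#' @export
read_ms <- function(path) {
  lines <- readLines(path)
  n <- as.integer(strsplit(lines[1], " +")[[1]][2])
  blocks <- which(lines == "//")
  lapply(blocks, function(b) {
    S <- as.integer(sub("segsites: *", "", lines[b + 1L]))
    if (S == 0L) return(matrix(0L, n, 0L))
    rows <- lines[(b + 3L):(b + 2L + n)]
    do.call(rbind, lapply(rows, function(r) {
      as.integer(strsplit(r, "")[[1]])
    }))
  })
}
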