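#' Declare a synthetic repeat family
#'
#' A family is described by an ancestral monomer length, a target genomic
#' copy number, an intra-family divergence (per-site substitution rate among
#' copies, the knob that controls how "old" the family looks in a cluster
#' layout), and a placement bias along the gene-density gradient: -1 seeks
#' gene-poor (pericentromere-like) regions, +1 seeks gene-rich regions, 0 is
#' uniform. `class_label` follows the dominant plant repeat superfamilies.
#'
#' @param name family name (unique within a library).
#' @param class_label one of "Gypsy-like", "Copia-like", "tandem", "other".
#' @param monomer_length monomer length in bp (>= 50).
#' @param target_copy_number copies per genome (>= 1).
#' @param intra_family_divergence substitutions per site in [0, 0.3].
#' @param placement_bias real in [-1, 1].
#' @return a `repeat_family_spec` object.
#' @export
repeat_family_spec <- function(name, class_label = "other",
                               monomer_length = 500L,
                               target_copy_number = 100L,
                               intra_family_divergence = 0.05,
                               placement_bias = 0) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  class_label <- match.arg(class_label,
                           c("Gypsy-like", "Copia-like", "tandem", "other"))
  if (monomer_length < 50) stop("monomer_length must be >= 50")
  if (target_copy_number < 1) stop("target_copy_number must be >= 1")
  if (intra_family_divergence < 0 || intra_family_divergence > 0.3)
    stop("intra_family_divergence must be in [0, 0.3]")
  if (abs(placement_bias) > 1) stop("placement_bias must be in [-1, 1]")
  structure(list(name = name, class_label = class_label,
                 monomer_length = as.integer(monomer_length),
                 target_copy_number = as.integer(target_copy_number),
                 intra_family_divergence = intra_family_divergence,
                 placement_bias = placement_bias),
            class = "repeat_family_spec")
}

#' Generate a repeat library from family specs
#'
#' Draws one ancestral monomer per family with uniform base composition.
#' Stands in for a curated repeat database: downstream annotation is a
#' best-hit search of cluster reads against these records.
#'
#' @param specs list of [repeat_family_spec()] objects.
#' @param seed integer seed; the library is a pure function of (specs, seed).
#' @return a `repeat_library`: data.frame with columns `name`, `class_label`,
#'   `monomer_length`, `target_copy_number`, `intra_family_divergence`,
#'   `placement_bias`, `sequence`.
#' @export
make_repeat_library <- function(specs, seed) {
  if (inherits(specs, "repeat_family_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 1L)
  nms <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("duplicate family names in specs: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  lib <- with_seed(seed, {
    seqs <- vapply(specs, function(sp) {
      paste(sample(c("A", "C", "G", "T"), sp$monomer_length, replace = TRUE),
            collapse = "")
    }, character(1))
    data.frame(
      name = nms,
      class_label = vapply(specs, `[[`, character(1), "class_label"),
      monomer_length = vapply(specs, `[[`, integer(1), "monomer_length"),
      target_copy_number = vapply(specs, `[[`, integer(1), "target_copy_number"),
      intra_family_divergence = vapply(specs, `[[`, numeric(1), "intra_family_divergence"),
      placement_bias = vapply(specs, `[[`, numeric(1), "placement_bias"),
      sequence = seqs,
      stringsAsFactors = FALSE
    )
  })
  class(lib) <- c("repeat_library", "data.frame")
  lib
}

#' Mutate a monomer into a set of family copies
#'
#' Substitution-only model: each copy mutates every site independently with
#' probability `divergence`, to one of the three other bases uniformly. No
#' indels, so copy length always equals monomer length and k-mer arithmetic
#' downstream stays exact.
#'
#' @param monomer character scalar over A/C/G/T.
#' @param n_copies number of copies (0 allowed, returns character(0)).
#' @param divergence per-site substitution probability in [0, 0.3].
#' @param seed integer seed.
#' @return character vector of `n_copies` sequences.
#' @export
evolve_family_copies <- function(monomer, n_copies, divergence, seed) {
  stopifnot(is.character(monomer), length(monomer) == 1L)
  if (divergence < 0 || divergence > 0.3) stop("divergence must be in [0, 0.3]")
  if (n_copies == 0) return(character(0))
  bases <- c("A", "C", "G", "T")
  tmpl <- strsplit(monomer, "")[[1]]
  L <- length(tmpl)
  with_seed(seed, {
    vapply(seq_len(n_copies), function(i) {
      hit <- which(runif(L) < divergence)
      if (length(hit)) {
        cur <- tmpl
        for (p in hit) cur[p] <- sample(bases[bases != cur[p]], 1L)
        paste(cur, collapse = "")
      } else paste(tmpl, collapse = "")
    }, character(1))
  })
}

# realized gene-coverage fraction per 1 kb bin of one chromosome
.gene_cov_bins <- function(len, genes, bin = 1000L) {
  nb <- ceiling(len / bin)
  cov <- numeric(nb)
  if (nrow(genes)) {
    ir <- IRanges::reduce(IRanges::IRanges(genes$start + 1L, genes$end))
    bins <- IRanges::IRanges(start = (seq_len(nb) - 1L) * bin + 1L,
                             end = pmin(seq_len(nb) * bin, len))
    ov <- IRanges::findOverlaps(bins, ir)
    if (length(ov)) {
      w <- IRanges::width(IRanges::pintersect(bins[S4Vectors::queryHits(ov)],
                                              ir[S4Vectors::subjectHits(ov)]))
      agg <- tapply(w, S4Vectors::queryHits(ov), sum)
      cov[as.integer(names(agg))] <- agg / IRanges::width(bins)[as.integer(names(agg))]
    }
  }
  cov
}

# smoothed local gene density (fraction, ~50 kb scale) used as insertion weight
.local_density <- function(cov) {
  if (length(cov) < 2) return(cov)
  k <- min(51L, length(cov))
  as.numeric(stats::filter(cov, rep(1 / k, k), sides = 2, circular = TRUE))
}

#' Build an annotated synthetic genome
#'
#' Genes are placed first along a smooth density gradient; repeat copies are
#' then inserted by overwriting background sequence, with family-specific
#' placement bias relative to the realized local gene density. Tandem
#' families are planted as one contiguous head-to-tail array at a single
#' locus. Every insertion is recorded in the truth table.
#'
#' @param library a `repeat_library` from [make_repeat_library()].
#' @param copy_plan named integer vector of copies per family; defaults to
#'   each family's `target_copy_number`.
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param gene_density list with `n_genes`, `gene_length` (bp) and `profile`,
#'   a function of the position fraction in [0, 1] returning a relative
#'   density (default: linear gradient, gene-rich at the chromosome start).
#' @param seed integer seed.
#' @return a `synthetic_genome`: list with `chromosomes` (named character),
#'   `genes` and `truth` (0-based half-open data.frames), and `library`.
#' @export
build_genome <- function(library, copy_plan = NULL, chrom_lengths,
                         gene_density = list(n_genes = 40L, gene_length = 3000L,
                                             profile = function(x) 1.5 - x),
                         seed = 1L) {
  stopifnot(inherits(library, "repeat_library"), length(chrom_lengths) >= 1L)
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  if (is.null(copy_plan)) {
    copy_plan <- library$target_copy_number
    names(copy_plan) <- library$name
  }
  copy_plan <- copy_plan[copy_plan > 0]
  bad <- setdiff(names(copy_plan), library$name)
  if (length(bad)) stop("copy_plan names not in library: ", paste(bad, collapse = ", "))
  glen <- sum(as.numeric(chrom_lengths))
  planned <- sum(vapply(names(copy_plan), function(f) {
    as.numeric(copy_plan[[f]]) * library$monomer_length[library$name == f]
  }, numeric(1)))
  if (planned >= glen)
    stop("planned repeat length (", planned, ") exceeds genome length (", glen, ")")

  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    chroms <- lapply(chrom_lengths, function(L) sample(bases, L, replace = TRUE))
    occ <- lapply(chrom_lengths, function(L) logical(L))
    gl <- as.integer(gene_density$gene_length)
    n_genes <- as.integer(gene_density$n_genes)
    prof <- gene_density$profile

    # dispersed copies: rejection sampling against a 1 kb density grid,
    # falling back to free-gap sampling when the genome is crowded
    dens <- NULL; dmax <- 1
    place_one <- function(len, bias, max_try = 500L) {
      for (i in seq_len(max_try)) {
        ch <- sample(names(chrom_lengths), 1L,
                     prob = as.numeric(chrom_lengths) / glen)
        L <- chrom_lengths[[ch]]
        if (len > L) next
        if (is.null(dens)) {
          nb <- ceiling(L / 1000)
          g <- pmax(prof((seq_len(nb) - 0.5) / nb), 0)
          g <- if (max(g) > 0) g / max(g) else rep(0.5, nb)
        } else g <- dens[[ch]] / dmax     # realized local gene density
        # log-linear insertion preference; |bias| = 1 is a strong seeker
        w <- exp(3 * bias * (2 * g - 1))
        w <- pmax(w, 1e-9)
        b <- sample.int(length(w), 1L, prob = w)
        s <- (b - 1L) * 1000L + sample.int(1000L, 1L) - 1L
        if (s + len > L) next
        if (any(occ[[ch]][(s + 1L):(s + len)])) next
        occ[[ch]][(s + 1L):(s + len)] <<- TRUE
        return(list(chrom = ch, start = s))
      }
      # free-gap fallback: uniform over feasible starts, bias ignored
      for (ch in sample(names(chrom_lengths))) {
        r <- rle(occ[[ch]])
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        free <- which(!r$values & r$lengths >= len)
        if (!length(free)) next
        pick <- free[sample.int(length(free), 1L,
                                prob = r$lengths[free] - len + 1L)]
        s <- starts[pick] - 1L + sample.int(r$lengths[pick] - len + 1L, 1L) - 1L
        occ[[ch]][(s + 1L):(s + len)] <<- TRUE
        return(list(chrom = ch, start = s))
      }
      NULL
    }

    # tandem arrays first: one large contiguous locus each, placed while the
    # genome is still empty so a long free gap is guaranteed to exist
    fams <- names(copy_plan)
    is_tandem <- vapply(fams, function(f)
      library$class_label[library$name == f] == "tandem", logical(1))
    truth <- list()
    emit <- function(df) truth[[length(truth) + 1L]] <<- df

    for (f in fams[is_tandem]) {
      row <- library[library$name == f, ]
      n <- as.integer(copy_plan[[f]])
      copies <- evolve_family_copies(row$sequence, n, row$intra_family_divergence,
                                     sample.int(.Machine$integer.max, 1L))
      loc <- place_one(n * row$monomer_length, row$placement_bias)
      if (is.null(loc)) stop("cannot place tandem family '", f,
                             "': genome over-filled")
      strand <- sample(c("+", "-"), 1L)
      for (i in seq_len(n)) {
        s <- loc$start + (i - 1L) * row$monomer_length
        cp <- if (strand == "+") copies[i] else .revcomp_chr(copies[i])
        chroms[[loc$chrom]][(s + 1L):(s + row$monomer_length)] <-
          strsplit(cp, "")[[1]]
        emit(data.frame(family = f, chrom = loc$chrom, start = s,
                        end = s + row$monomer_length, strand = strand,
                        stringsAsFactors = FALSE))
      }
    }

    # genes next, along the density gradient, avoiding tandem loci
    genes <- list()
    for (ch in names(chrom_lengths)) {
      L <- chrom_lengths[[ch]]
      ng <- max(1L, round(n_genes * L / glen))
      nbin <- max(10L, L %/% 10000L)
      mids <- (seq_len(nbin) - 0.5) / nbin
      w <- pmax(prof(mids), 0)
      if (sum(w) == 0) w <- rep(1, nbin)
      starts <- integer(0)
      for (i in seq_len(ng * 10L)) {
        if (length(starts) >= ng) break
        b <- sample.int(nbin, 1L, prob = w)
        s <- (b - 1L) * (L %/% nbin) + sample.int(max(1L, L %/% nbin), 1L) - 1L
        if (s + gl > L) next
        if (any(occ[[ch]][(s + 1L):(s + gl)])) next
        if (!any(abs(starts - s) < gl)) starts <- c(starts, s)
      }
      if (length(starts))
        genes[[ch]] <- data.frame(chrom = ch, start = sort(starts),
                                  end = sort(starts) + gl, stringsAsFactors = FALSE)
    }
    genes <- if (length(genes)) do.call(rbind, genes) else
      data.frame(chrom = character(0), start = integer(0), end = integer(0))
    rownames(genes) <- NULL
    for (i in seq_len(nrow(genes)))
      occ[[genes$chrom[i]]][(genes$start[i] + 1L):genes$end[i]] <- TRUE

    dens <- lapply(names(chrom_lengths), function(ch)
      .local_density(.gene_cov_bins(chrom_lengths[[ch]],
                                    genes[genes$chrom == ch, , drop = FALSE])))
    names(dens) <- names(chrom_lengths)
    dmax <- max(1e-9, max(unlist(dens)))

    for (f in fams[!is_tandem]) {
      row <- library[library$name == f, ]
      n <- as.integer(copy_plan[[f]])
      copies <- evolve_family_copies(row$sequence, n, row$intra_family_divergence,
                                     sample.int(.Machine$integer.max, 1L))
      for (i in seq_len(n)) {
        loc <- place_one(row$monomer_length, row$placement_bias)
        if (is.null(loc)) stop("cannot place family '", f,
                               "': genome over-filled")
        strand <- sample(c("+", "-"), 1L)
        cp <- if (strand == "+") copies[i] else .revcomp_chr(copies[i])
        chroms[[loc$chrom]][(loc$start + 1L):(loc$start + row$monomer_length)] <-
          strsplit(cp, "")[[1]]
        emit(data.frame(family = f, chrom = loc$chrom, start = loc$start,
                        end = loc$start + row$monomer_length, strand = strand,
                        stringsAsFactors = FALSE))
      }
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(family = character(0), chrom = character(0),
                 start = integer(0), end = integer(0), strand = character(0))
    rownames(truth) <- NULL
    structure(list(
      chromosomes = vapply(chroms, paste, character(1), collapse = ""),
      genes = genes, truth = truth, library = library
    ), class = "synthetic_genome")
  })
}

.revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Configure a two-population simulation
#'
#' @param n_individuals_per_pop individuals per population (>= 2).
#' @param pop_labels two population labels.
#' @param snp_count number of biallelic SNP markers (>= 2).
#' @param snp_divergence Balding-Nichols style F in [0, 0.5]: each
#'   population's allele frequency is drawn around a shared ancestral
#'   frequency p as Beta(p(1-F)/F, (1-p)(1-F)/F); F = 0 means identical
#'   frequencies.
#' @param repeat_effect multiplicative copy-number shift of population 2
#'   relative to population 1, a scalar or named-per-family vector (> 0).
#' @param heterozygosity_rate fraction of calls forced heterozygous.
#' @param seed integer seed.
#' @return a `population_config` list.
#' @export
population_config <- function(n_individuals_per_pop = 47L,
                              pop_labels = c("SS", "NSS"),
                              snp_count = 1585L,
                              snp_divergence = 0.2,
                              repeat_effect = 1.0,
                              heterozygosity_rate = 0.02,
                              seed = 1L) {
  stopifnot(n_individuals_per_pop >= 2L, snp_count >= 2L,
            length(pop_labels) == 2L,
            snp_divergence >= 0, snp_divergence <= 0.5,
            heterozygosity_rate >= 0, heterozygosity_rate <= 1)
  if (any(repeat_effect <= 0)) stop("repeat_effect must be > 0")
  structure(list(n_individuals_per_pop = as.integer(n_individuals_per_pop),
                 pop_labels = pop_labels, snp_count = as.integer(snp_count),
                 snp_divergence = snp_divergence, repeat_effect = repeat_effect,
                 heterozygosity_rate = heterozygosity_rate,
                 seed = as.integer(seed)),
            class = "population_config")
}

#' Simulate a structured two-population panel
#'
#' Per-family copy numbers are Poisson draws around population means, where
#' population 2's mean is population 1's mean times `repeat_effect` (1 = no
#' divergence). SNP genotypes use a symmetric Balding-Nichols draw: ancestral
#' frequency p ~ Uniform(0.1, 0.9) per marker, each population's frequency
#' ~ Beta(p(1-F)/F, (1-p)(1-F)/F) with F = `snp_divergence`; inbred calls are
#' homozygous for an allele drawn at the population frequency, with
#' heterozygous calls injected at `heterozygosity_rate`.
#'
#' @param genome a `synthetic_genome` (family means taken from its truth
#'   table) or a named numeric vector of family mean copy numbers.
#' @param config a [population_config()].
#' @return list with `copy_number` (individuals x families), `genotypes`
#'   (individuals x markers, allele-pair calls like "AA"/"AG"), `labels`
#'   (data.frame individual, population).
#' @export
simulate_population <- function(genome, config) {
  stopifnot(inherits(config, "population_config"))
  means <- if (inherits(genome, "synthetic_genome")) {
    tab <- table(genome$truth$family)
    stats::setNames(as.numeric(tab), names(tab))
  } else {
    stopifnot(is.numeric(genome), !is.null(names(genome)))
    genome
  }
  fams <- names(means)
  eff <- config$repeat_effect
  if (length(eff) == 1L && is.null(names(eff)))
    eff <- stats::setNames(rep(eff, length(fams)), fams)
  if (any(eff <= 0)) stop("repeat_effect must be > 0")
  eff <- eff[fams]
  eff[is.na(eff)] <- 1.0
  n <- config$n_individuals_per_pop
  pops <- rep(config$pop_labels, each = n)
  inds <- sprintf("%s_%02d", pops, c(seq_len(n), seq_len(n)))

  with_seed(config$seed, {
    cn <- matrix(0L, nrow = 2L * n, ncol = length(fams),
                 dimnames = list(inds, fams))
    for (j in seq_along(fams)) {
      mu <- c(rep(means[j], n), rep(means[j] * eff[j], n))
      cn[, j] <- rpois(2L * n, mu)
    }
    Fst <- config$snp_divergence
    m <- config$snp_count
    p_anc <- runif(m, 0.1, 0.9)
    pfreq <- matrix(0, nrow = 2L, ncol = m)
    for (k in 1:2) {
      pfreq[k, ] <- if (Fst == 0) p_anc else
        rbeta(m, p_anc * (1 - Fst) / Fst, (1 - p_anc) * (1 - Fst) / Fst)
    }
    alleles <- t(vapply(seq_len(m), function(j) sample(c("A", "C", "G", "T"), 2L),
                        character(2)))
    geno <- matrix("", nrow = 2L * n, ncol = m,
                   dimnames = list(inds, sprintf("snp_%04d", seq_len(m))))
    for (j in seq_len(m)) {
      for (k in 1:2) {
        rows <- ((k - 1L) * n + 1L):(k * n)
        a1 <- rbinom(n, 1L, pfreq[k, j])     # 1 = reference allele
        call <- ifelse(a1 == 1L, strrep(alleles[j, 1L], 2L),
                       strrep(alleles[j, 2L], 2L))
        het <- runif(n) < config$heterozygosity_rate
        call[het] <- paste0(alleles[j, 1L], alleles[j, 2L])
        geno[rows, j] <- call
      }
    }
    list(copy_number = cn, genotypes = geno,
         labels = data.frame(individual = inds, population = pops,
                             stringsAsFactors = FALSE))
  })
}

#' Shotgun-sequence a genome into labelled skim reads
#'
#' Uniform start positions (chromosome chosen proportional to length),
#' uniform strand; minus-strand reads are emitted reverse-complemented.
#' With `paired = TRUE`, fragments of `2 * read_length + insert` yield two
#' reads sharing a `fragment_id` (forward from the fragment start, reverse
#' complement from its end).
#'
#' @param genome a `synthetic_genome` or named character vector of sequences.
#' @param n_reads number of reads to emit.
#' @param read_length read length in bp (<= shortest chromosome).
#' @param seed integer seed.
#' @param individual,population labels carried on every read.
#' @param paired emit read pairs (n_reads must then be even).
#' @param insert inner insert size for pairs.
#' @return a `ReadSet` data.frame: read_id, individual, population,
#'   fragment_id, chrom, start, end, strand, sequence.
#' @export
shotgun_reads <- function(genome, n_reads, read_length = 150L, seed = 1L,
                          individual = "ind1", population = "pop1",
                          paired = FALSE, insert = 50L) {
  chroms <- if (inherits(genome, "synthetic_genome")) genome$chromosomes else genome
  stopifnot(is.character(chroms), !is.null(names(chroms)))
  lens <- nchar(chroms)
  span <- if (paired) 2L * read_length + insert else read_length
  if (span > min(lens))
    stop("read/fragment span (", span, ") exceeds shortest chromosome (",
         min(lens), ")")
  cols <- c("read_id", "individual", "population", "fragment_id",
            "chrom", "start", "end", "strand", "sequence")
  if (n_reads == 0) {
    out <- data.frame(read_id = character(0), individual = character(0),
                      population = character(0), fragment_id = character(0),
                      chrom = character(0), start = integer(0), end = integer(0),
                      strand = character(0), sequence = character(0))
    class(out) <- c("ReadSet", "data.frame")
    return(out)
  }
  nfrag <- if (paired) {
    if (n_reads %% 2L != 0L) stop("paired output needs an even n_reads")
    n_reads %/% 2L
  } else n_reads
  out <- with_seed(seed, {
    ch <- sample(names(chroms), nfrag, replace = TRUE, prob = lens / sum(lens))
    start <- vapply(ch, function(c) sample.int(lens[[c]] - span + 1L, 1L) - 1L,
                    integer(1))
    strand <- sample(c("+", "-"), nfrag, replace = TRUE)
    frag_id <- sprintf("%s_f%06d", individual, seq_len(nfrag))
    take <- function(c, s, e) substr(chroms[[c]], s + 1L, e)
    if (!paired) {
      seqs <- mapply(take, ch, start, start + read_length)
      seqs[strand == "-"] <- vapply(seqs[strand == "-"], .revcomp_chr, character(1))
      data.frame(read_id = sprintf("%s_r%06d", individual, seq_len(nfrag)),
                 individual = individual, population = population,
                 fragment_id = frag_id, chrom = ch, start = start,
                 end = start + read_length, strand = strand, sequence = unname(seqs),
                 stringsAsFactors = FALSE)
    } else {
      s1 <- start; s2 <- start + read_length + insert
      r1 <- mapply(take, ch, s1, s1 + read_length)
      r2 <- vapply(mapply(take, ch, s2, s2 + read_length), .revcomp_chr, character(1))
      flip <- strand == "-" # fragment orientation swaps which mate is forward
      df1 <- data.frame(read_id = paste0(frag_id, "/1"), individual = individual,
                        population = population, fragment_id = frag_id,
                        chrom = ch, start = s1, end = s1 + read_length,
                        strand = ifelse(flip, "-", "+"),
                        sequence = ifelse(flip, vapply(unname(r1), .revcomp_chr, character(1)),
                                          unname(r1)),
                        stringsAsFactors = FALSE)
      df2 <- data.frame(read_id = paste0(frag_id, "/2"), individual = individual,
                        population = population, fragment_id = frag_id,
                        chrom = ch, start = s2, end = s2 + read_length,
                        strand = ifelse(flip, "+", "-"),
                        sequence = ifelse(flip, vapply(unname(r2), .revcomp_chr, character(1)),
                                          unname(r2)),
                        stringsAsFactors = FALSE)
      rbind(df1, df2)
    }
  })
  rownames(out) <- NULL
  out <- out[, cols]
  class(out) <- c("ReadSet", "data.frame")
  out
}

#' Down-sample a read set without replacement
#'
#' For paired input (duplicated `fragment_id`s) at most one read per fragment
#' is kept, emulating skim down-sampling that takes one read from each
#' sequenced pair.
#'
#' @param reads a `ReadSet` data.frame.
#' @param n number of reads to keep.
#' @param seed integer seed.
#' @return a `ReadSet` with exactly `n` rows.
#' @export
downsample_reads <- function(reads, n, seed = 1L) {
  stopifnot(is.data.frame(reads))
  if (n == 0) {
    out <- reads[0, , drop = FALSE]
    class(out) <- c("ReadSet", "data.frame")
    return(out)
  }
  with_seed(seed, {
    pool <- reads
    if ("fragment_id" %in% names(reads) && anyDuplicated(reads$fragment_id)) {
      keep <- tapply(seq_len(nrow(reads)), reads$fragment_id,
                     function(ix) if (length(ix) == 1L) ix else sample(ix, 1L))
      pool <- reads[sort(as.integer(keep)), , drop = FALSE]
    }
    if (n > nrow(pool))
      stop("requested ", n, " reads but only ", nrow(pool),
           " are available (one per fragment)")
    out <- pool[sort(sample.int(nrow(pool), n)), , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("ReadSet", "data.frame")
    out
  })
}

#' Label reads by their true repeat family of origin
#'
#' Assigns each read the family whose truth placement it overlaps the most,
#' provided the overlap is at least `min_overlap` bases; otherwise
#' "background". The default of 54 bp is the shortest perfect alignment
#' that can reach the default 100-bit graph-edge threshold, so a read
#' counts as family-derived exactly when it carries enough family sequence
#' for the pipeline to see. Used by purity checks against clustering
#' output.
#'
#' @param reads a `ReadSet` carrying source coordinates.
#' @param genome the `synthetic_genome` the reads were drawn from.
#' @param min_overlap minimum overlap in bp to assign a family.
#' @return character vector of family labels, one per read.
#' @export
true_read_family <- function(reads, genome, min_overlap = 54L) {
  stopifnot(inherits(genome, "synthetic_genome"))
  truth <- genome$truth
  out <- rep("background", nrow(reads))
  if (!nrow(truth) || !nrow(reads)) return(out)
  for (ch in unique(reads$chrom)) {
    ri <- which(reads$chrom == ch)
    ti <- truth[truth$chrom == ch, , drop = FALSE]
    if (!nrow(ti)) next
    rir <- IRanges::IRanges(reads$start[ri] + 1L, reads$end[ri])
    tir <- IRanges::IRanges(ti$start + 1L, ti$end)
    ov <- IRanges::findOverlaps(rir, tir)
    if (!length(ov)) next
    w <- IRanges::width(IRanges::pintersect(rir[S4Vectors::queryHits(ov)],
                                            tir[S4Vectors::subjectHits(ov)]))
    df <- data.frame(q = S4Vectors::queryHits(ov),
                     fam = ti$family[S4Vectors::subjectHits(ov)], w = w)
    agg <- stats::aggregate(w ~ q + fam, df, sum)
    best <- agg[order(agg$q, -agg$w, agg$fam), ]
    best <- best[!duplicated(best$q), ]
    hit <- best$w >= min_overlap
    out[ri[best$q[hit]]] <- best$fam[hit]
  }
  out
}
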