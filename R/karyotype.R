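# Karyotype model for male Drosophila melanogaster spermatocytes.
#
# All analytic expectations used downstream (centromere dot counts, cluster
# intensities, entity counts at M I, telomere dot counts, and the
# random-segregation null) derive from this model rather than being hard-coded
# at the point of use.

#' Male *Drosophila melanogaster* karyotype
#'
#' Builds the 2n = 8 male karyotype (chr2, chr3, chr4, X, Y): two homologs of
#' each autosome and one copy each of X and Y. Each chromatid contributes one
#' centromere "unit" whose relative fluorescence weight is 1.0, except the Y
#' centromere which carries a twofold weight by default (the Y centromere is
#' about twice as bright as the others in Cid/Cenp-A imaging). Every chromatid
#' carries two telomere ends.
#'
#' @param phase Cell-cycle phase, `"G1"` (one chromatid per homolog) or
#'   `"G2"` (two sister chromatids per homolog, as in spermatocytes after
#'   premeiotic S phase).
#' @param y_centromere_weight Relative intensity of the chrY centromere unit.
#'   The default 2.0 encodes the twofold brighter Y centromere; it is exposed
#'   as a parameter for sensitivity analyses.
#' @return An object of class `karyotype_spec`: a list with a `chromosomes`
#'   data frame (name, size class, homolog copies, centromere weight,
#'   telomere ends per chromatid, satellite labels) and the `phase`.
#' @examples
#' k <- karyotype_male("G2")
#' expected_telomere_dot_count(k)  # 32
#' @export
karyotype_male <- function(phase = c("G1", "G2"), y_centromere_weight = 2) {
  phase <- match.arg(phase)
  stopifnot(y_centromere_weight > 0)
  chromosomes <- data.frame(
    name = c("chr2", "chr3", "chr4", "chrX", "chrY"),
    size_class = c("large_autosome", "large_autosome", "dot", "sex", "sex"),
    copies = c(2L, 2L, 2L, 1L, 1L),
    centromere_weight = c(1, 1, 1, 1, y_centromere_weight),
    telomere_ends = 2L,
    stringsAsFactors = FALSE
  )
  satellites <- list(
    sat_359  = "chrX",
    sat_1686 = c("chr2", "chr3")
  )
  structure(
    list(chromosomes = chromosomes, satellites = satellites, phase = phase),
    class = "karyotype_spec"
  )
}

#' @export
print.karyotype_spec <- function(x, ...) {
  cat("Male D. melanogaster karyotype (", x$phase, ", 2n = ",
      sum(x$chromosomes$copies), ")\n", sep = "")
  print(x$chromosomes, row.names = FALSE)
  invisible(x)
}

chromatids_per_homolog <- function(karyotype) {
  if (karyotype$phase == "G2") 2L else 1L
}

#' Centromere units of a karyotype
#'
#' One unit per chromatid per homolog copy, with its relative intensity
#' weight.
#'
#' @param karyotype A [karyotype_male()] object.
#' @return Data frame with columns `chromosome`, `homolog`, `chromatid`,
#'   `weight`.
#' @export
centromere_units <- function(karyotype) {
  stopifnot(inherits(karyotype, "karyotype_spec"))
  nc <- chromatids_per_homolog(karyotype)
  ch <- karyotype$chromosomes
  out <- do.call(rbind, lapply(seq_len(nrow(ch)), function(i) {
    expand.grid(chromosome = ch$name[i], homolog = seq_len(ch$copies[i]),
                chromatid = seq_len(nc), stringsAsFactors = FALSE)
  }))
  out$weight <- ch$centromere_weight[match(out$chromosome, ch$name)]
  out
}

#' Define a centromere cluster
#'
#' A cluster is a set of centromere units described per homolog copy: which
#' chromosome, which homolog, and how many of its chromatids contribute.
#'
#' @param ... Entries of the form `list(chromosome, homolog, chromatids)`, or
#'   a single data frame with those three columns.
#' @return A `cluster_composition` object (data frame with columns
#'   `chromosome`, `homolog`, `chromatids`).
#' @examples
#' # the Aa cluster: all centromeres of one large-autosome bivalent in G2
#' cluster_composition(list("chr2", 1, 2), list("chr2", 2, 2))
#' @export
cluster_composition <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.data.frame(args[[1]])) {
    df <- args[[1]]
  } else {
    df <- do.call(rbind, lapply(args, function(m) {
      data.frame(chromosome = m[[1]], homolog = as.integer(m[[2]]),
                 chromatids = as.integer(m[[3]]), stringsAsFactors = FALSE)
    }))
  }
  stopifnot(all(c("chromosome", "homolog", "chromatids") %in% names(df)))
  if (nrow(df) == 0L) stop("invalid cluster: empty member list")
  if (any(df$chromatids < 1L)) stop("invalid cluster: chromatid count < 1")
  class(df) <- c("cluster_composition", class(df))
  df
}

# Expand a cluster to per-unit rows and validate against the karyotype.
cluster_units <- function(cluster, karyotype) {
  units <- centromere_units(karyotype)
  nc <- chromatids_per_homolog(karyotype)
  ch <- karyotype$chromosomes
  rows <- lapply(seq_len(nrow(cluster)), function(i) {
    chrom <- cluster$chromosome[i]
    j <- match(chrom, ch$name)
    if (is.na(j)) stop("invalid cluster: unknown chromosome ", chrom)
    if (cluster$homolog[i] > ch$copies[j])
      stop("invalid cluster: homolog ", cluster$homolog[i], " of ", chrom,
           " does not exist")
    if (cluster$chromatids[i] > nc)
      stop("invalid cluster: ", cluster$chromatids[i], " chromatids of ",
           chrom, " requested in phase ", karyotype$phase)
    data.frame(chromosome = chrom, homolog = cluster$homolog[i],
               n = cluster$chromatids[i],
               weight = ch$centromere_weight[j], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Expected number of centromere dots for a cluster partition
#'
#' Given a partition of all centromere units into clusters, the expected dot
#' count is simply the number of clusters; the value of this function is the
#' validation that the partition covers every unit exactly once (no overlap,
#' no omission), so that dot-count expectations for named stages are derived
#' rather than asserted.
#'
#' @param karyotype A [karyotype_male()] object.
#' @param partition List of [cluster_composition()] objects jointly covering
#'   all centromere units exactly once.
#' @return Integer dot count.
#' @seealso [canonical_partition()] for the named stages.
#' @export
expected_centromere_dot_count <- function(karyotype, partition) {
  stopifnot(inherits(karyotype, "karyotype_spec"), is.list(partition))
  nc <- chromatids_per_homolog(karyotype)
  used <- lapply(partition, cluster_units, karyotype = karyotype)
  used <- do.call(rbind, used)
  tot <- stats::aggregate(n ~ chromosome + homolog, data = used, FUN = sum)
  full <- unique(centromere_units(karyotype)[c("chromosome", "homolog")])
  key <- function(d) paste(d$chromosome, d$homolog)
  if (!setequal(key(tot), key(full)) || any(tot$n != nc))
    stop("invalid partition: centromere units not covered exactly once")
  length(partition)
}

#' Canonical centromere cluster partitions
#'
#' Named stages of centromere de-clustering: `"one_dot"` (a single chromocenter
#' cluster of all centromeres), `"three_dot"` (clusters Aa, Ab and XY4: one per
#' large-autosome bivalent plus the merged chrX/chrY/chr4 cluster),
#' `"four_dot_bivalent"` (the naive one-cluster-per-bivalent configuration
#' used for the 1.5-fold intensity expectation), and `"eight_dot"` (one dot
#' per homolog copy, sister centromeres unresolved).
#'
#' @param karyotype A [karyotype_male()] object.
#' @param stage One of `"one_dot"`, `"three_dot"`, `"four_dot_bivalent"`,
#'   `"eight_dot"`.
#' @return Named list of [cluster_composition()] objects.
#' @export
canonical_partition <- function(karyotype,
                                stage = c("one_dot", "three_dot",
                                          "four_dot_bivalent", "eight_dot")) {
  stage <- match.arg(stage)
  nc <- chromatids_per_homolog(karyotype)
  cc <- function(...) cluster_composition(...)
  Aa <- cc(list("chr2", 1, nc), list("chr2", 2, nc))
  Ab <- cc(list("chr3", 1, nc), list("chr3", 2, nc))
  XY <- cc(list("chrX", 1, nc), list("chrY", 1, nc))
  four <- cc(list("chr4", 1, nc), list("chr4", 2, nc))
  XY4 <- cc(list("chrX", 1, nc), list("chrY", 1, nc),
            list("chr4", 1, nc), list("chr4", 2, nc))
  switch(stage,
    one_dot = list(all = cc(list("chr2", 1, nc), list("chr2", 2, nc),
                            list("chr3", 1, nc), list("chr3", 2, nc),
                            list("chr4", 1, nc), list("chr4", 2, nc),
                            list("chrX", 1, nc), list("chrY", 1, nc))),
    three_dot = list(Aa = Aa, Ab = Ab, XY4 = XY4),
    four_dot_bivalent = list(Aa = Aa, Ab = Ab, XY = XY, four = four),
    eight_dot = {
      units <- unique(centromere_units(karyotype)[c("chromosome", "homolog")])
      p <- lapply(seq_len(nrow(units)), function(i)
        cc(list(units$chromosome[i], units$homolog[i], nc)))
      names(p) <- paste0(units$chromosome, ".", units$homolog)
      p
    })
}

#' Expected integrated intensity of a centromere cluster
#'
#' Sum over cluster members of centromere unit weight times chromatid
#' multiplicity, in relative units where one ordinary chromatid centromere
#' contributes 1.0.
#'
#' @param cluster A [cluster_composition()].
#' @param karyotype A [karyotype_male()] object.
#' @return Expected intensity in relative units.
#' @examples
#' k <- karyotype_male("G2")
#' p <- canonical_partition(k, "four_dot_bivalent")
#' expected_cluster_intensity(p$XY, k) / expected_cluster_intensity(p$Aa, k)
#' @export
expected_cluster_intensity <- function(cluster, karyotype) {
  if (!inherits(cluster, "cluster_composition"))
    cluster <- cluster_composition(cluster)
  u <- cluster_units(cluster, karyotype)
  sum(u$n * u$weight)
}

#' Intensity ratio of two clusters
#'
#' @param cluster_a,cluster_b [cluster_composition()] objects.
#' @param karyotype A [karyotype_male()] object.
#' @return `expected_cluster_intensity(cluster_a) /
#'   expected_cluster_intensity(cluster_b)`.
#' @export
cluster_intensity_ratio <- function(cluster_a, cluster_b, karyotype) {
  expected_cluster_intensity(cluster_a, karyotype) /
    expected_cluster_intensity(cluster_b, karyotype)
}

#' Pairing configuration of the four bivalents
#'
#' Whether homolog conjunction is intact for each bivalent at the onset of
#' meiosis I. A disrupted bivalent contributes two univalents to the entity
#' count.
#'
#' @param chr2,chr3,chr4,XY Logical; is the bivalent's conjunction intact?
#' @return A `pairing_config` object.
#' @export
pairing_config <- function(chr2 = TRUE, chr3 = TRUE, chr4 = TRUE, XY = TRUE) {
  structure(list(chr2 = isTRUE(chr2), chr3 = isTRUE(chr3),
                 chr4 = isTRUE(chr4), XY = isTRUE(XY)),
            class = "pairing_config")
}

#' Expected number of chromosomal entities at meiosis I onset
#'
#' Each bivalent with intact conjunction counts as one entity; each disrupted
#' bivalent counts as two univalents. With all four bivalents intact this is
#' 4; with conjunction lost on the three autosomal bivalents but not the sex
#' bivalent it is 7; with all conjunction lost it is 8.
#'
#' @param karyotype A [karyotype_male()] object.
#' @param pairing A [pairing_config()].
#' @return Integer entity count.
#' @export
expected_entity_count <- function(karyotype, pairing = pairing_config()) {
  stopifnot(inherits(pairing, "pairing_config"))
  sum(vapply(pairing, function(intact) if (intact) 1L else 2L, integer(1)))
}

#' Telomere units of a karyotype
#'
#' @param karyotype A [karyotype_male()] object.
#' @param phase Optional phase override (`"G1"` or `"G2"`).
#' @return Character vector of telomere unit ids, one per chromatid end,
#'   e.g. `"chr2.h1.c1.end2"`.
#' @export
telomere_units <- function(karyotype, phase = karyotype$phase) {
  ch <- karyotype$chromosomes
  nc <- if (phase == "G2") 2L else 1L
  unlist(lapply(seq_len(nrow(ch)), function(i) {
    g <- expand.grid(h = seq_len(ch$copies[i]), c = seq_len(nc),
                     e = seq_len(ch$telomere_ends[i]))
    sprintf("%s.h%d.c%d.end%d", ch$name[i], g$h, g$c, g$e)
  }))
}

#' Expected number of telomere dots per nucleus
#'
#' Fully resolved, the count is chromosomes x 2 ends x chromatids per
#' chromosome: 16 in G1 and 32 in G2 for the male karyotype. A clustering
#' (list of groups of telomere unit ids) collapses each group to a single
#' dot.
#'
#' @param karyotype A [karyotype_male()] object.
#' @param phase `"G1"` or `"G2"`; defaults to the karyotype's phase.
#' @param clustering List of character vectors of telomere unit ids (see
#'   [telomere_units()]); empty list means fully resolved.
#' @return Integer dot count.
#' @export
expected_telomere_dot_count <- function(karyotype, phase = karyotype$phase,
                                        clustering = list()) {
  units <- telomere_units(karyotype, phase)
  grouped <- unlist(clustering)
  if (length(grouped)) {
    bad <- setdiff(grouped, units)
    if (length(bad))
      stop("clustering references nonexistent telomere unit(s): ",
           paste(bad, collapse = ", "))
    if (anyDuplicated(grouped))
      stop("clustering assigns a telomere unit to more than one group")
  }
  length(units) - length(grouped) + length(clustering)
}

#' Expected number of satellite dots
#'
#' Number of distinct dots expected for a satellite label when associations
#' between its carrier loci are fully disrupted: one dot per homolog copy of
#' each carrier chromosome (4 for the 1.686 satellite on chr2 and chr3; 1 for
#' the 359-bp satellite on chrX in males).
#'
#' @param karyotype A [karyotype_male()] object.
#' @param satellite Satellite label (`"sat_1686"` or `"sat_359"`).
#' @return Integer dot count.
#' @export
expected_satellite_dot_count <- function(karyotype, satellite = "sat_1686") {
  carriers <- karyotype$satellites[[satellite]]
  if (is.null(carriers)) stop("unknown satellite label: ", satellite)
  ch <- karyotype$chromosomes
  sum(ch$copies[match(carriers, ch$name)])
}

#' Random-segregation null distribution over pole-ratio classes
#'
#' The distribution of unordered pole ratios a:b (a >= b, a + b = n) when
#' each of n independent units segregates to one of two poles with
#' probability 1/2. `"analytic"` mode enumerates the 2^n equally likely
#' pole assignments exactly (capped at n = 30); `"montecarlo"` mode draws
#' `n_cells` cells with a seeded generator and returns empirical class
#' frequencies.
#'
#' @param n_units Number of independently segregating units (>= 1).
#' @param mode `"analytic"` or `"montecarlo"`.
#' @param n_cells Number of simulated cells (montecarlo mode).
#' @param seed Integer seed (montecarlo mode).
#' @return Data frame with columns `class` (e.g. `"5:3"`), `a`, `b`,
#'   `probability`, and for montecarlo mode `count`.
#' @examples
#' random_segregation_null(8)  # 4:4 has probability 70/256
#' @export
random_segregation_null <- function(n_units,
                                    mode = c("analytic", "montecarlo"),
                                    n_cells = NULL, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_units >= 1)
  n_units <- as.integer(n_units)
  a <- seq.int(ceiling(n_units / 2), n_units)
  b <- n_units - a
  classes <- data.frame(class = paste0(a, ":", b), a = a, b = b,
                        stringsAsFactors = FALSE)
  if (mode == "analytic") {
    if (n_units > 30)
      stop("analytic enumeration capped at n_units = 30; use montecarlo")
    # each of the 2^n assignments has probability 2^-n; an unordered class
    # {a, b} aggregates choose(n, a) assignments, doubled when a != b
    w <- choose(n_units, classes$a) * ifelse(classes$a == classes$b, 1, 2)
    classes$probability <- w / 2^n_units
  } else {
    stopifnot(!is.null(n_cells), n_cells >= 1, !is.null(seed))
    old <- local_seed(seed)
    on.exit(restore_seed(old))
    k <- stats::rbinom(n_cells, n_units, 0.5)
    amax <- pmax(k, n_units - k)
    cnt <- vapply(classes$a, function(ai) sum(amax == ai), numeric(1))
    classes$count <- cnt
    classes$probability <- cnt / n_cells
  }
  classes
}

#' Write / read a karyotype specification
#'
#' Serializes the karyotype as a human-editable YAML file.
#'
#' @param karyotype A [karyotype_male()] object.
#' @param path File path.
#' @return `read_karyotype` returns a `karyotype_spec`.
#' @export
write_karyotype <- function(karyotype, path) {
  yaml::write_yaml(list(
    phase = karyotype$phase,
    chromosomes = karyotype$chromosomes,
    satellites = karyotype$satellites
  ), path, column.major = FALSE)
  invisible(path)
}

#' @rdname write_karyotype
#' @export
read_karyotype <- function(path) {
  raw <- yaml::read_yaml(path)
  ch <- do.call(rbind, lapply(raw$chromosomes, as.data.frame))
  ch$copies <- as.integer(ch$copies)
  ch$telomere_ends <- as.integer(ch$telomere_ends)
  structure(list(chromosomes = ch, satellites = raw$satellites,
                 phase = raw$phase),
            class = "karyotype_spec")
}
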