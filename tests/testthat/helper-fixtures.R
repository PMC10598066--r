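# Shared fixture builders: everything is generated in code at test time.

# expression matrix from a genes x samples numeric matrix with
# self-describing column names ("case_4wk_1", ...)
fixture_expr <- function(signals) {
  samples <- catifunnel:::parse_sample_ids(colnames(signals))
  expr_matrix(signals, samples)
}

# small matrix: one gene per behaviour class, case 3 reps / control 1 rep
fixture_screen_matrices <- function() {
  genes <- c("flat", "up8", "up10", "down8", "shared_up", "low")
  build <- function(strain, n_rep, planted) {
    cols <- list()
    for (tp in c(4, 8, 10)) {
      for (r in seq_len(n_rep)) {
        v <- c(flat = 100, up8 = 100, up10 = 100, down8 = 90,
               shared_up = 100, low = 3)
        if (tp == 8) {
          if (planted) {
            v["up8"] <- 200; v["down8"] <- 30
          }
          v["shared_up"] <- 250
        }
        if (tp == 10 && planted) v["up10"] <- 180
        cols[[sprintf("%s_%dwk_%d", strain, tp, r)]] <- v
      }
    }
    m <- do.call(cbind, cols)
    rownames(m) <- genes
    fixture_expr(m)
  }
  list(case = build("case", 3, TRUE), control = build("control", 1, FALSE))
}

# write a VCF text fixture and return its path
fixture_vcf <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotations\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "ICR"), collapse = "\t")
  )
  path <- tempfile("fix", tmpdir = dir, fileext = ".vcf")
  writeLines(c(header, lines), path)
  path
}

vcf_line <- function(chrom, pos, ref, alt, info, gt, fmt = "GT") {
  paste(chrom, pos, ".", ref, alt, ".", "PASS", info, fmt, gt, sep = "\t")
}

# a small expression sim spec with planted counts scaled to n_genes
small_expr_spec <- function(n_genes, seed, ...) {
  k <- max(1L, n_genes %/% 10L)
  expression_sim_spec(n_genes = n_genes, seed = seed,
                      n_case_only_up = k, n_shared_up = k,
                      n_case_only_down = k, ...)
}

# random variant table for property tests
random_variants <- function(n, assembly = "asmA") {
  chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
  pos <- sample.int(1e6, n)
  al <- catifunnel:::random_alleles(n)
  variant_records(
    chrom, pos, al$ref, al$alt,
    genotype = sample(c("hom_alt", "het", "hom_ref", "missing"), n, TRUE),
    gene = sprintf("G%04d", sample.int(9999, n)),
    so_terms = sample(names(so_impact_table()), n, TRUE),
    assembly = assembly
  )
}
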