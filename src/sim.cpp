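#include <Rcpp.h>
using namespace Rcpp;

// One generation of gametes for the forward-time crossover/BGC simulator.
//
// haps: 2N x L matrix of 0/1 alleles, individual i owns rows 2i and 2i+1
// parents: n_off x 2 (0-based individual indices; column 1 = mother,
//          column 2 = father); offspring o receives the maternal gamete in
//          output row 2o and the paternal gamete in row 2o+1.
// causal_col: 0-based column of the causal SNP, or -1 when absent.
//
// Meiosis: at most one crossover in the region.  The crossover probability
// depends on the parent's genotype at the causal SNP (background, het x10,
// hot-homozygote x20 under the default multipliers).  When the hotspot is
// active (at least one hot allele) the breakpoint is drawn from a truncated
// normal centered at the hotspot; otherwise uniformly on the region.  With
// probability bgc_prob conditional on a crossover, the initiating haplotype
// (the hot one in heterozygotes) has a Gaussian-length conversion tract
// centered at the breakpoint overwritten from its homolog before the flanks
// are exchanged -- a heterozygous causal SNP inside the tract converts
// hot -> cold.
//
// The RNG decisions are made gamete by gamete in a first pass; alleles are
// then filled column by column (both matrices are column-major, so this
// keeps reads and writes contiguous).
// [[Rcpp::export]]
List sim_gametes(const IntegerMatrix& haps, const NumericVector& pos,
                 int causal_col, int hot_allele,
                 const IntegerMatrix& parents,
                 double p_background, double het_mult, double hom_mult,
                 double hotspot_center, double bp_sigma,
                 double bgc_prob, double tract_mean, double tract_sigma,
                 double region_length) {
  const int L = haps.ncol();
  const int n_off = parents.nrow();
  const int n_gam = 2 * n_off;
  IntegerMatrix gametes(n_gam, L);
  IntegerVector ev_parent(n_gam), ev_het(n_gam), ev_recomb(n_gam),
      ev_allele(n_gam), ev_bgc(n_gam);
  NumericVector ev_bp(n_gam);

  // per-gamete meiosis decisions
  std::vector<int> g_src(n_gam), g_init(n_gam), g_other(n_gam);
  std::vector<double> g_bp(n_gam), g_lo(n_gam), g_hi(n_gam);
  std::vector<unsigned char> g_rec(n_gam), g_bgcf(n_gam), g_left(n_gam);

  for (int o = 0; o < n_off; ++o) {
    for (int side = 0; side < 2; ++side) {
      const int g = 2 * o + side;
      const int p = parents(o, side);
      const int r1 = 2 * p, r2 = 2 * p + 1;
      int hotcount = 0;
      bool het = false;
      if (causal_col >= 0) {
        hotcount = (haps(r1, causal_col) == hot_allele) +
                   (haps(r2, causal_col) == hot_allele);
        het = hotcount == 1;
      }
      double p_cross = p_background *
          (hotcount == 0 ? 1.0 : (hotcount == 1 ? het_mult : hom_mult));
      ev_parent[g] = p;
      ev_het[g] = het ? 1 : 0;
      if (unif_rand() >= p_cross) {
        g_rec[g] = 0;
        g_src[g] = (unif_rand() < 0.5) ? r1 : r2;
        ev_recomb[g] = 0;
        ev_bgc[g] = 0;
        ev_bp[g] = NA_REAL;
      } else {
        g_rec[g] = 1;
        const bool hot_active = causal_col >= 0 && hotcount >= 1;
        double bp;
        if (hot_active) {
          do {
            bp = R::rnorm(hotspot_center, bp_sigma);
          } while (bp <= 0.0 || bp >= region_length);
        } else {
          bp = unif_rand() * region_length;
        }
        int init;
        if (het) {
          init = (haps(r1, causal_col) == hot_allele) ? r1 : r2;
        } else {
          init = (unif_rand() < 0.5) ? r1 : r2;
        }
        g_init[g] = init;
        g_other[g] = (init == r1) ? r2 : r1;
        g_bp[g] = bp;
        const bool bgc = unif_rand() < bgc_prob;
        g_bgcf[g] = bgc ? 1 : 0;
        if (bgc) {
          double len = R::rnorm(tract_mean, tract_sigma);
          if (len < 0.0) len = 0.0;
          g_lo[g] = bp - len / 2.0;
          g_hi[g] = bp + len / 2.0;
        } else {
          g_lo[g] = 0.0;
          g_hi[g] = -1.0;
        }
        g_left[g] = (unif_rand() < 0.5) ? 1 : 0;
        ev_recomb[g] = 1;
        ev_bgc[g] = bgc ? 1 : 0;
        ev_bp[g] = bp;
      }
    }
  }

  // allele fill, column by column
  for (int c = 0; c < L; ++c) {
    const int* hcol = &haps(0, c);
    int* gcol = &gametes(0, c);
    const double pc = pos[c];
    for (int g = 0; g < n_gam; ++g) {
      if (!g_rec[g]) {
        gcol[g] = hcol[g_src[g]];
      } else {
        const bool left = pc < g_bp[g];
        const int init = g_init[g];
        const int src = (left == (bool)g_left[g]) ? init : g_other[g];
        int val = hcol[src];
        if (src == init && g_bgcf[g] && pc >= g_lo[g] && pc <= g_hi[g])
          val = hcol[g_other[g]];   // conversion tract repaired from homolog
        gcol[g] = val;
      }
    }
  }

  if (causal_col >= 0) {
    for (int g = 0; g < n_gam; ++g) ev_allele[g] = gametes(g, causal_col);
  } else {
    for (int g = 0; g < n_gam; ++g) ev_allele[g] = NA_INTEGER;
  }
  return List::create(
      _["gametes"] = gametes,
      _["parent"] = ev_parent, _["het"] = ev_het,
      _["recombinant"] = ev_recomb, _["causal_allele"] = ev_allele,
      _["bgc"] = ev_bgc, _["breakpoint"] = ev_bp);
}
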