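#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Coalescent simulation of one scaffold for a fixed 5-taxon species-tree shape
// (((A,B),C),D),O with node times t1 < t2 < t3 < t4 (generations) and one
// diploid per species (haplotypes 2s, 2s+1 for species s = 0..4).
//
// The scaffold is cut into blocks (breakpoints supplied by the caller); each
// block gets an independent genealogy, emulating free recombination between
// blocks and complete linkage within. Introgression tracts are realized by
// grafting the recipient haplotype lineage(s) onto the donor haplotype's
// ancestral lineage at the admixture time, so a tract's true age is exactly
// its specified admixture time.
//
// Mutation: JC69 with per-branch Bernoulli placement (binomial count, uniform
// positions, new base uniform among the other three). At the rates used the
// process is effectively infinite-sites.

static const int NHAP = 10;

struct Genealogy {
  // up to 19 binary-coalescent nodes + 2 graft nodes
  std::vector<double> time;
  std::vector<int> parent;
  int root;
};

// one population interval of the species tree
struct Pop { double start, end, ne; int parent_pop; };

static void build_pops(const double *t, const double *ne, Pop *pops) {
  // tips 0..4 = A, B, C, D, O; 5 = anc(AB); 6 = anc(ABC); 7 = anc(ABCD); 8 = root
  double tip_end[5] = { t[0], t[0], t[1], t[2], t[3] };
  int tip_par[5] = { 5, 5, 6, 7, 8 };
  for (int i = 0; i < 5; ++i) pops[i] = { 0.0, tip_end[i], ne[i], tip_par[i] };
  pops[5] = { t[0], t[1], ne[5], 6 };
  pops[6] = { t[1], t[2], ne[6], 7 };
  pops[7] = { t[2], t[3], ne[7], 8 };
  pops[8] = { t[3], R_PosInf, ne[8], -1 };
}

// simulate the genealogy of the supplied tip lineages (others grafted later)
static void sim_genealogy(const Pop *pops, const bool *tip_active,
                          Genealogy &g) {
  g.time.assign(NHAP, 0.0);
  g.parent.assign(NHAP, -1);
  std::vector<int> members[9];
  for (int h = 0; h < NHAP; ++h)
    if (tip_active[h]) members[h / 2].push_back(h);
  for (int p = 0; p < 9; ++p) {
    std::vector<int> &m = members[p];
    double tcur = pops[p].start;
    while ((int)m.size() >= 2) {
      double k = (double)m.size();
      double rate = k * (k - 1.0) / 2.0 / (2.0 * pops[p].ne);
      tcur += exp_rand() / rate;
      if (tcur >= pops[p].end) break;
      int i = (int)(unif_rand() * m.size());
      int j = (int)(unif_rand() * (m.size() - 1));
      if (j >= i) ++j;
      int node = (int)g.time.size();
      g.time.push_back(tcur);
      g.parent.push_back(-1);
      g.parent[m[i]] = node;
      g.parent[m[j]] = node;
      if (i > j) std::swap(i, j);
      m[j] = node;          // replace one child by the new node
      m.erase(m.begin() + i);
    }
    if (pops[p].parent_pop >= 0)
      for (size_t i = 0; i < m.size(); ++i)
        members[pops[p].parent_pop].push_back(m[i]);
  }
  g.root = -1;
  for (int n = (int)g.time.size() - 1; n >= 0; --n)
    if (g.parent[n] == -1) { g.root = n; break; }
}

// attach lineage `tip` onto the lineage ancestral to haplotype `donor` at time ta
static void graft(Genealogy &g, int tip, int donor, double ta) {
  int u = donor;
  while (g.parent[u] != -1 && g.time[g.parent[u]] <= ta) u = g.parent[u];
  int p = g.parent[u];
  int node = (int)g.time.size();
  g.time.push_back(ta);
  g.parent.push_back(p);
  g.parent[u] = node;
  g.parent[tip] = node;
  if (p == -1) g.root = node;
}

// drop JC69 mutations over the genealogy; write tip sequences into hap[,]
static void mutate_block(const Genealogy &g, double mu, int off, int len,
                         unsigned char **hap) {
  int nn = (int)g.time.size();
  std::vector< std::vector<int> > children(nn);
  for (int n = 0; n < nn; ++n)
    if (g.parent[n] != -1) children[g.parent[n]].push_back(n);
  std::vector< std::vector<unsigned char> > seq(nn);
  seq[g.root].resize(len);
  for (int i = 0; i < len; ++i)
    seq[g.root][i] = (unsigned char)(unif_rand() * 4.0);
  // iterative DFS from root
  std::vector<int> stack;
  stack.push_back(g.root);
  while (!stack.empty()) {
    int u = stack.back(); stack.pop_back();
    for (size_t ci = 0; ci < children[u].size(); ++ci) {
      int c = children[u][ci];
      seq[c] = seq[u];
      double blen = g.time[u] - g.time[c];
      if (blen > 0) {
        double pmut = -expm1(-mu * blen);
        int nmut = (int)R::rbinom((double)len, pmut);
        for (int k = 0; k < nmut; ++k) {
          int pos = (int)(unif_rand() * len);
          unsigned char cur = seq[c][pos];
          seq[c][pos] = (unsigned char)((cur + 1 + (int)(unif_rand() * 3.0)) % 4);
        }
      }
      if (c < NHAP) {
        std::memcpy(hap[c] + off, seq[c].data(), len);
        seq[c].clear(); seq[c].shrink_to_fit();
      } else {
        stack.push_back(c);
      }
    }
    seq[u].clear(); seq[u].shrink_to_fit();
  }
}

// [[Rcpp::export]]
RawMatrix cpp_sim_scaffold(IntegerVector breakpoints,
                           NumericVector split_times, NumericVector ne_pops,
                           double mu,
                           IntegerVector blk_donor_hap,
                           IntegerVector blk_rec_species,
                           IntegerVector blk_zygosity,
                           NumericVector blk_admix_time) {
  int nb = breakpoints.size() - 1;
  int L = breakpoints[nb];
  Pop pops[9];
  build_pops(split_times.begin(), ne_pops.begin(), pops);
  RawMatrix out(L, NHAP);
  unsigned char *hap[NHAP];
  for (int h = 0; h < NHAP; ++h)
    hap[h] = (unsigned char *)RAW(out) + (R_xlen_t)L * h;
  Genealogy g;
  for (int b = 0; b < nb; ++b) {
    int off = breakpoints[b], len = breakpoints[b + 1] - breakpoints[b];
    bool tip_active[NHAP];
    for (int h = 0; h < NHAP; ++h) tip_active[h] = true;
    int donor = blk_donor_hap[b];     // -1 when no tract in this block
    if (donor >= 0) {
      int r1 = 2 * blk_rec_species[b];
      tip_active[r1] = false;
      if (blk_zygosity[b] == 2) tip_active[r1 + 1] = false;
    }
    sim_genealogy(pops, tip_active, g);
    if (donor >= 0) {
      int r1 = 2 * blk_rec_species[b];
      graft(g, r1, donor, blk_admix_time[b]);
      if (blk_zygosity[b] == 2) {
        // homozygous (fixed) tract: second copy identical to the first
        g.parent[r1 + 1] = g.parent[r1];
      }
    }
    mutate_block(g, mu, off, len, hap);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_extract_snps(RawMatrix hap) {
  // all segregating sites, including multiallelic ones (a joint caller
  // reports them; downstream stages filter on n_alleles as appropriate).
  // ref = first allele encountered; geno = non-reference allele count per
  // sample; gtcode = i1*8 + i2 with allele indices into the site allele list.
  int L = hap.nrow();
  const unsigned char *p = (const unsigned char *)RAW(hap);
  std::vector<int> pos, nall, geno, gtcode;
  std::vector<std::string> refv, altv;
  const char *bases = "ACGT";
  for (int i = 0; i < L; ++i) {
    unsigned char al[4];
    int na = 0;
    int idx[NHAP];
    for (int h = 0; h < NHAP; ++h) {
      unsigned char a = p[i + (R_xlen_t)L * h];
      int k = 0;
      while (k < na && al[k] != a) ++k;
      if (k == na) al[na++] = a;
      idx[h] = k;
    }
    if (na < 2) continue;  // invariant
    pos.push_back(i);
    nall.push_back(na);
    refv.push_back(std::string(1, bases[al[0]]));
    std::string alt;
    for (int k = 1; k < na; ++k) {
      if (k > 1) alt += ',';
      alt += bases[al[k]];
    }
    altv.push_back(alt);
    for (int s = 0; s < 5; ++s) {
      int i1 = idx[2 * s], i2 = idx[2 * s + 1];
      geno.push_back((i1 > 0) + (i2 > 0));
      gtcode.push_back(i1 * 8 + i2);
    }
  }
  int n = (int)pos.size();
  IntegerMatrix gm(5, n), gc(5, n);
  if (n) {
    std::copy(geno.begin(), geno.end(), gm.begin());
    std::copy(gtcode.begin(), gtcode.end(), gc.begin());
  }
  return List::create(_["pos"] = wrap(pos), _["ref"] = wrap(refv),
                      _["alt"] = wrap(altv), _["n_alleles"] = wrap(nall),
                      _["geno"] = gm, _["gtcode"] = gc);
}

// [[Rcpp::export]]
CharacterVector cpp_consensus(RawMatrix hap) {
  // diploid consensus with IUPAC ambiguity codes for heterozygous sites
  int L = hap.nrow();
  const unsigned char *p = (const unsigned char *)RAW(hap);
  // code for unordered base pair {i,j}, bases A=0 C=1 G=2 T=3
  static const char amb[4][4] = { { 'A', 'M', 'R', 'W' },
                                  { 'M', 'C', 'S', 'Y' },
                                  { 'R', 'S', 'G', 'K' },
                                  { 'W', 'Y', 'K', 'T' } };
  CharacterVector out(5);
  std::string s(L, 'N');
  for (int sp = 0; sp < 5; ++sp) {
    const unsigned char *h1 = p + (R_xlen_t)L * (2 * sp);
    const unsigned char *h2 = p + (R_xlen_t)L * (2 * sp + 1);
    for (int i = 0; i < L; ++i) s[i] = amb[h1[i]][h2[i]];
    out[sp] = s;
  }
  return out;
}
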