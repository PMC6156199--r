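#include <Rcpp.h>
#include <vector>
#include <string>

// Simplified RNA folding energy model used by the built-in engine:
// Watson-Crick and wobble pairs score GC -3, AU -2, GU -1 kcal/mol, each
// stacked pair (i,j)/(i+1,j-1) adds -1, hairpin loops need >= 3 unpaired
// nucleotides, no pseudoknots. The minimum free energy over all secondary
// structures is computed by dynamic programming:
//   V(i,j) = energy given i pairs j
//          = e(i,j) + min(0, W(i+1,j-1), V(i+1,j-1) + stack)
//   W(i,j) = min(W(i,j-1), min_k W(i,k-1) + V(k,j))
// which scores exactly the same quantity as exhaustive enumeration of all
// structures under this model.

static const double STACK = -1.0;
static const double INF = 1e9;

static double pair_energy(char a, char b) {
    if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return -3.0;
    if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return -2.0;
    if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return -1.0;
    return 1.0;  // sentinel: not pairable
}

// [[Rcpp::export]]
double fold_mfe_cpp(std::string seq) {
    const int n = (int) seq.size();
    if (n < 5) return 0.0;
    std::vector<double> V((size_t) n * n, INF);
    std::vector<double> W((size_t) n * n, 0.0);
    for (int span = 4; span < n; ++span) {
        for (int i = 0; i + span < n; ++i) {
            const int j = i + span;
            const double pe = pair_energy(seq[i], seq[j]);
            if (pe < 0) {
                double best = 0.0;  // interior left unpaired (hairpin)
                const double wi = W[(size_t)(i + 1) * n + (j - 1)];
                if (wi < best) best = wi;
                const double vi = V[(size_t)(i + 1) * n + (j - 1)];
                if (vi < INF / 2 && vi + STACK < best) best = vi + STACK;
                V[(size_t) i * n + j] = pe + best;
            }
            double w = W[(size_t) i * n + (j - 1)];
            for (int k = i; k + 4 <= j; ++k) {
                const double vk = V[(size_t) k * n + j];
                if (vk < INF / 2) {
                    const double left = (k > i) ? W[(size_t) i * n + (k - 1)] : 0.0;
                    if (left + vk < w) w = left + vk;
                }
            }
            W[(size_t) i * n + j] = w;
        }
    }
    const double e = W[(size_t) 0 * n + (n - 1)];
    return e < 0.0 ? e : 0.0;
}
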