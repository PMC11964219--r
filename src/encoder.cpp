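// Transformer encoder forward/backward.
// Hidden states are (B*L) x d, sequence-major: sequence b occupies rows
// (b-1)*L .. b*L-1. Mirrors the reference R implementation exactly
// (verified by equivalence tests); dropout draws come from R's RNG so a
// single set.seed() makes whole training runs reproducible. Training
// caches stay on the C++ side behind an external pointer - copying them
// into R lists dominates the step time otherwise.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;

static const double LN_EPS = 1e-5;
static const double NEG_BIG = -1e30;

// wrap an arma vec as a plain R numeric vector (not an n x 1 matrix), so
// gradient shapes match the parameter shapes on the R side
static NumericVector nv(const vec& v) {
    return NumericVector(v.begin(), v.end());
}

struct LayerCache {
    mat Xin, Q, K, V, Pall, Cc, mAttn, xhat1, X1, Z1, s, A1, mFF, xhat2;
    vec inv1, inv2;
};

struct EncCache {
    mat xhatE, mEmb;
    vec invE;
    std::vector<LayerCache> blocks;
    arma::imat Tm;
    int B = 0, L = 0;
    bool hasDropout = false;
};

static mat layernorm_f(const mat& X, const vec& g, const vec& b,
                       mat& xhat, vec& inv) {
    vec mu = arma::mean(X, 1);
    mat xc = X.each_col() - mu;
    vec var = arma::mean(arma::square(xc), 1);
    inv = 1.0 / arma::sqrt(var + LN_EPS);
    xhat = xc.each_col() % inv;
    mat Y = xhat.each_row() % g.t();
    Y.each_row() += b.t();
    return Y;
}

// returns dX; fills dG, dB
static mat layernorm_b(const mat& dY, const mat& xhat, const vec& inv,
                       const vec& g, vec& dG, vec& dB) {
    mat dXhat = dY.each_row() % g.t();
    vec m1 = arma::mean(dXhat, 1);
    vec m2 = arma::mean(dXhat % xhat, 1);
    mat dX = dXhat;
    dX.each_col() -= m1;
    dX -= xhat.each_col() % m2;
    dX.each_col() %= inv;
    dG = arma::sum(dY % xhat, 0).t();
    dB = arma::sum(dY, 0).t();
    return dX;
}

static mat dropout_mask(arma::uword n, arma::uword d, double rate) {
    // column-major fill from R's RNG, matching the R reference
    NumericVector u = runif((int)(n * d));
    mat m(n, d);
    std::memcpy(m.memptr(), u.begin(), n * d * sizeof(double));
    m.transform([rate](double x) {
        return x >= rate ? 1.0 / (1.0 - rate) : 0.0;
    });
    return m;
}

// [[Rcpp::export(name = ".cppEncode")]]
List cppEncode(List params, List cfgL, IntegerMatrix TmR, bool train) {
    const int B = TmR.nrow(), L = TmR.ncol();
    const int d = as<int>(cfgL["embedDim"]);
    const int H = as<int>(cfgL["nHeads"]);
    const int nBlocks = as<int>(cfgL["nBlocks"]);
    const double drop = as<double>(cfgL["dropout"]);
    const int dh = d / H;
    const double scl = 1.0 / std::sqrt((double)dh);
    const int n = B * L;

    mat tokEmb = as<mat>(params["tokEmb"]);
    mat posEmb = as<mat>(params["posEmb"]);
    List blocks = params["blocks"];

    EncCache* cache = train ? new EncCache() : nullptr;
    if (train) {
        cache->B = B; cache->L = L;
        cache->Tm.set_size(B, L);
        for (int b = 0; b < B; ++b)
            for (int l = 0; l < L; ++l) cache->Tm(b, l) = TmR(b, l);
        cache->blocks.resize(nBlocks);
        cache->hasDropout = drop > 0;
    }

    mat X(n, d);
    for (int b = 0; b < B; ++b)
        for (int l = 0; l < L; ++l)
            X.row(b * L + l) = tokEmb.row(TmR(b, l)) + posEmb.row(l);
    {
        mat xhatE; vec invE;
        X = layernorm_f(X, as<vec>(params["lnEmbG"]),
                        as<vec>(params["lnEmbB"]), xhatE, invE);
        if (train) { cache->xhatE = std::move(xhatE);
                     cache->invE = std::move(invE); }
    }
    if (train && drop > 0) {
        cache->mEmb = dropout_mask(n, d, drop);
        X %= cache->mEmb;
    }
    std::vector<arma::uvec> padCols(B);
    for (int b = 0; b < B; ++b) {
        std::vector<arma::uword> pc;
        for (int l = 0; l < L; ++l)
            if (TmR(b, l) == 0) pc.push_back(l);
        padCols[b] = arma::uvec(pc);
    }

    List layers(train ? 0 : nBlocks);
    for (int i = 0; i < nBlocks; ++i) {
        List blk = blocks[i];
        LayerCache* lc = train ? &cache->blocks[i] : nullptr;
        mat Q = X * as<mat>(blk["Wq"]);
        Q.each_row() += as<vec>(blk["bq"]).t();
        mat K = X * as<mat>(blk["Wk"]);
        K.each_row() += as<vec>(blk["bk"]).t();
        mat V = X * as<mat>(blk["Wv"]);
        V.each_row() += as<vec>(blk["bv"]).t();
        mat Cc(n, d, arma::fill::zeros);
        mat Pall;
        if (train) Pall.set_size(n, (arma::uword)H * L);
        for (int b = 0; b < B; ++b) {
            const int r0 = b * L, r1 = (b + 1) * L - 1;
            const arma::uvec& pc = padCols[b];
            for (int h = 0; h < H; ++h) {
                const int c0 = h * dh, c1 = (h + 1) * dh - 1;
                mat S = Q.submat(r0, c0, r1, c1) *
                        K.submat(r0, c0, r1, c1).t() * scl;
                if (pc.n_elem) S.cols(pc).fill(NEG_BIG);
                S.each_col() -= arma::max(S, 1);
                mat E = arma::exp(S);
                vec rs = arma::sum(E, 1);
                mat P = E.each_col() / rs;
                Cc.submat(r0, c0, r1, c1) = P * V.submat(r0, c0, r1, c1);
                if (train)
                    Pall.submat(r0, (arma::uword)h * L, r1,
                                (arma::uword)(h + 1) * L - 1) =
                        std::move(P);
            }
        }
        mat O = Cc * as<mat>(blk["Wo"]);
        O.each_row() += as<vec>(blk["bo"]).t();
        if (train && drop > 0) {
            lc->mAttn = dropout_mask(n, d, drop);
            O %= lc->mAttn;
        }
        mat xhat1; vec inv1;
        mat X1 = layernorm_f(X + O, as<vec>(blk["ln1g"]),
                             as<vec>(blk["ln1b"]), xhat1, inv1);
        mat Z1 = X1 * as<mat>(blk["W1"]);
        Z1.each_row() += as<vec>(blk["b1"]).t();
        mat s = 1.0 / (1.0 + arma::exp(-Z1));
        mat A1 = Z1 % s;
        mat Fo = A1 * as<mat>(blk["W2"]);
        Fo.each_row() += as<vec>(blk["b2"]).t();
        if (train && drop > 0) {
            lc->mFF = dropout_mask(n, d, drop);
            Fo %= lc->mFF;
        }
        mat xhat2; vec inv2;
        mat X2 = layernorm_f(X1 + Fo, as<vec>(blk["ln2g"]),
                             as<vec>(blk["ln2b"]), xhat2, inv2);
        if (train) {
            lc->Xin = std::move(X);
            lc->Q = std::move(Q); lc->K = std::move(K);
            lc->V = std::move(V); lc->Pall = std::move(Pall);
            lc->Cc = std::move(Cc);
            lc->xhat1 = std::move(xhat1); lc->inv1 = std::move(inv1);
            lc->X1 = std::move(X1); lc->Z1 = std::move(Z1);
            lc->s = std::move(s); lc->A1 = std::move(A1);
            lc->xhat2 = std::move(xhat2); lc->inv2 = std::move(inv2);
        } else {
            layers[i] = X2;
        }
        X = std::move(X2);
    }
    List out = List::create(_["H"] = X, _["layers"] = layers,
                            _["B"] = B, _["L"] = L, _["Tm"] = TmR);
    if (train)
        out["cache"] = XPtr<EncCache>(cache, true);
    return out;
}

// [[Rcpp::export(name = ".cppBackward")]]
List cppBackward(List params, List cfgL, List fw, NumericMatrix dHr) {
    const int d = as<int>(cfgL["embedDim"]);
    const int H = as<int>(cfgL["nHeads"]);
    const int nBlocks = as<int>(cfgL["nBlocks"]);
    const int dh = d / H;
    const double scl = 1.0 / std::sqrt((double)dh);
    XPtr<EncCache> cache(as<SEXP>(fw["cache"]));
    const int B = cache->B, L = cache->L;
    const int n = B * L;
    const bool hasDrop = cache->hasDropout;
    List blocks = params["blocks"];

    mat dX(dHr.begin(), n, d);
    List gBlocks(nBlocks);
    for (int i = nBlocks - 1; i >= 0; --i) {
        List blk = blocks[i];
        LayerCache& cc = cache->blocks[i];
        mat W2 = as<mat>(blk["W2"]), W1 = as<mat>(blk["W1"]);
        mat Wo = as<mat>(blk["Wo"]);
        mat Wq = as<mat>(blk["Wq"]), Wk = as<mat>(blk["Wk"]),
            Wv = as<mat>(blk["Wv"]);
        vec dG2, dB2;
        mat dRes2 = layernorm_b(dX, cc.xhat2, cc.inv2,
                                as<vec>(blk["ln2g"]), dG2, dB2);
        mat dF = dRes2;
        if (hasDrop) dF %= cc.mFF;
        mat gW2 = cc.A1.t() * dF;
        vec gb2 = arma::sum(dF, 0).t();
        mat dA1 = dF * W2.t();
        mat dZ1 = dA1 % (cc.s % (1.0 + cc.Z1 % (1.0 - cc.s)));
        mat gW1 = cc.X1.t() * dZ1;
        vec gb1 = arma::sum(dZ1, 0).t();
        mat dX1 = dRes2 + dZ1 * W1.t();
        vec dG1, dB1;
        mat dRes1 = layernorm_b(dX1, cc.xhat1, cc.inv1,
                                as<vec>(blk["ln1g"]), dG1, dB1);
        mat dO = dRes1;
        if (hasDrop) dO %= cc.mAttn;
        mat gWo = cc.Cc.t() * dO;
        vec gbo = arma::sum(dO, 0).t();
        mat dCc = dO * Wo.t();
        mat dQ(n, d, arma::fill::zeros), dK(n, d, arma::fill::zeros),
            dV(n, d, arma::fill::zeros);
        for (int b = 0; b < B; ++b) {
            const int r0 = b * L, r1 = (b + 1) * L - 1;
            for (int h = 0; h < H; ++h) {
                const int c0 = h * dh, c1 = (h + 1) * dh - 1;
                mat P = cc.Pall.submat(r0, (arma::uword)h * L, r1,
                                       (arma::uword)(h + 1) * L - 1);
                mat dOh = dCc.submat(r0, c0, r1, c1);
                mat dP = dOh * cc.V.submat(r0, c0, r1, c1).t();
                dV.submat(r0, c0, r1, c1) = P.t() * dOh;
                vec rowdot = arma::sum(dP % P, 1);
                mat dS = P % (dP.each_col() - rowdot);
                dQ.submat(r0, c0, r1, c1) =
                    dS * cc.K.submat(r0, c0, r1, c1) * scl;
                dK.submat(r0, c0, r1, c1) =
                    dS.t() * cc.Q.submat(r0, c0, r1, c1) * scl;
            }
        }
        List g = List::create(
            _["Wq"] = cc.Xin.t() * dQ, _["bq"] = nv(arma::sum(dQ, 0).t()),
            _["Wk"] = cc.Xin.t() * dK, _["bk"] = nv(arma::sum(dK, 0).t()),
            _["Wv"] = cc.Xin.t() * dV, _["bv"] = nv(arma::sum(dV, 0).t()),
            _["Wo"] = gWo, _["bo"] = nv(gbo),
            _["ln1g"] = nv(dG1), _["ln1b"] = nv(dB1),
            _["W1"] = gW1, _["b1"] = nv(gb1), _["W2"] = gW2,
            _["b2"] = nv(gb2), _["ln2g"] = nv(dG2), _["ln2b"] = nv(dB2));
        gBlocks[i] = g;
        dX = dRes1 + dQ * Wq.t() + dK * Wk.t() + dV * Wv.t();
    }
    if (hasDrop) dX %= cache->mEmb;
    vec dGE, dBE;
    mat dEmb = layernorm_b(dX, cache->xhatE, cache->invE,
                           as<vec>(params["lnEmbG"]), dGE, dBE);
    mat tokEmb = as<mat>(params["tokEmb"]);
    mat posEmb = as<mat>(params["posEmb"]);
    mat gTok(tokEmb.n_rows, d, arma::fill::zeros);
    mat gPos(posEmb.n_rows, d, arma::fill::zeros);
    for (int b = 0; b < B; ++b)
        for (int l = 0; l < L; ++l) {
            gTok.row(cache->Tm(b, l)) += dEmb.row(b * L + l);
            gPos.row(l) += dEmb.row(b * L + l);
        }
    return List::create(
        _["tokEmb"] = gTok, _["posEmb"] = gPos,
        _["lnEmbG"] = nv(dGE), _["lnEmbB"] = nv(dBE),
        _["blocks"] = gBlocks);
}
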