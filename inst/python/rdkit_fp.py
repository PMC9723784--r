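"""Fingerprint backend for the 'toolkit_default' scheme.

Reads a TSV of (name, smiles) on stdin-free file paths, writes a TSV of
(name, n_bits, comma-separated sorted on-bit indices).  Invoked by the R
package; kept dependency-minimal on purpose.
"""
import argparse
import sys


def main() -> int:
    ap = argparse.ArgumentParser()
    ap.add_argument("--fptype", choices=["maccs", "topological"], default="maccs")
    ap.add_argument("--nbits", type=int, default=2048)
    ap.add_argument("infile")
    ap.add_argument("outfile")
    args = ap.parse_args()

    try:
        from rdkit import Chem
        from rdkit.Chem import MACCSkeys, RDKFingerprint
    except ImportError:
        sys.stderr.write("RDKit is not importable\n")
        return 3

    rows = []
    with open(args.infile, encoding="utf-8") as fh:
        header = fh.readline()
        if not header.startswith("name\tsmiles"):
            sys.stderr.write("expected header 'name\\tsmiles'\n")
            return 2
        for line in fh:
            line = line.rstrip("\n")
            if not line:
                continue
            name, smiles = line.split("\t")[:2]
            mol = Chem.MolFromSmiles(smiles)
            if mol is None:
                sys.stderr.write(f"RDKit could not parse SMILES for '{name}': {smiles}\n")
                return 4
            if args.fptype == "maccs":
                fp = MACCSkeys.GenMACCSKeys(mol)
            else:
                fp = RDKFingerprint(mol, fpSize=args.nbits)
            bits = sorted(fp.GetOnBits())
            rows.append((name, fp.GetNumBits(), ",".join(map(str, bits))))

    with open(args.outfile, "w", encoding="utf-8") as out:
        out.write("name\tn_bits\tbits\n")
        for name, nbits, bits in rows:
            out.write(f"{name}\t{nbits}\t{bits}\n")
    return 0


if __name__ == "__main__":
    sys.exit(main())
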