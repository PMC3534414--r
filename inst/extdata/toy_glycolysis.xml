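<?xml version="1.0"?>
<pathway name="path:rn00010" org="rn" number="10" title="Glycolysis (toy excerpt)">
  <entry id="1" name="cpd:C00267" type="compound"><graphics name="alpha-D-Glucose"/></entry>
  <entry id="2" name="cpd:C00221" type="compound"><graphics name="beta-D-Glucose"/></entry>
  <entry id="3" name="cpd:C00668" type="compound"><graphics name="alpha-D-Glucose 6-phosphate"/></entry>
  <entry id="4" name="cpd:C00085" type="compound"><graphics name="D-Fructose 6-phosphate"/></entry>
  <entry id="5" name="cpd:C00002" type="compound"><graphics name="ATP"/></entry>
  <entry id="6" name="cpd:C00008" type="compound"><graphics name="ADP"/></entry>
  <entry id="7" name="ko:K00845 ec:2.7.1.2" type="ortholog" reaction="rn:R01786"/>
  <entry id="8" name="ko:K00845 ec:2.7.1.2" type="ortholog" reaction="rn:R02189"/>
  <entry id="9" name="ko:K01810 ec:5.3.1.9" type="ortholog" reaction="rn:R00771"/>
  <reaction id="11" name="rn:R01786" type="irreversible">
    <substrate id="1" name="cpd:C00267"/>
    <substrate id="5" name="cpd:C00002"/>
    <product id="3" name="cpd:C00668"/>
    <product id="6" name="cpd:C00008"/>
  </reaction>
  <reaction id="12" name="rn:R02189" type="irreversible">
    <substrate id="2" name="cpd:C00221"/>
    <substrate id="5" name="cpd:C00002"/>
    <product id="3" name="cpd:C00668"/>
    <product id="6" name="cpd:C00008"/>
  </reaction>
  <reaction id="13" name="rn:R00771" type="reversible">
    <substrate id="3" name="cpd:C00668"/>
    <product id="4" name="cpd:C00085"/>
  </reaction>
</pathway>
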