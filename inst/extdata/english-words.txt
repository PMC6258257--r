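# Compact common-English word list for the dictionary membership test.
# One lowercase word per line; '#' lines are comments. Hyphenated forms are
# dictionary words only when listed as a whole. Honorific stems are included
# because token lookup strips trailing periods.
a
able
about
above
academic
accept
accepted
access
account
acknowledge
acknowledged
acknowledgement
acknowledgements
acknowledgment
acknowledgments
across
act
active
activity
additional
address
advice
adviser
advisor
after
again
against
agree
agreement
aid
al
all
almost
along
also
although
always
am
among
amount
an
analyses
analysis
analyzed
and
animal
animals
another
antibodies
antibody
antigen
antigens
antiserum
antisera
any
anyone
apparatus
appreciate
appreciated
appreciation
are
around
article
as
assay
assays
assistance
assistant
assisted
associate
association
at
attribute
attributes
author
authors
authority
available
award
awarded
back
based
be
became
because
become
been
before
began
behalf
being
believe
below
best
between
beyond
biology
blood
board
body
bone
both
brain
bring
broad
brought
but
buffer
by
called
came
can
cancer
cannot
care
careful
carefully
carried
carry
case
cases
cell
cells
center
centre
certain
chair
chairman
chemical
chemicals
clinical
clone
clones
cocktail
cocktails
code
collaboration
colleague
colleagues
collect
collected
collection
college
come
comment
comments
committee
common
community
company
complete
completed
conduct
conducted
confirm
confirmed
consider
considered
construct
constructive
constructs
contain
contained
contains
content
contract
contribute
contributed
contribution
contributions
control
controls
core
could
council
counsel
critical
critically
culture
cultures
current
data
database
day
days
dean
deep
deeply
department
der
design
designed
detailed
develop
developed
development
did
differ
different
direct
directed
direction
director
discussion
discussions
disease
do
doctor
does
doing
donate
donated
donation
donations
done
donor
donors
down
dr
draft
drafts
during
each
early
editing
editor
editorial
education
effort
efforts
either
en
end
equipment
especially
et
even
every
excellent
exchange
expert
expertise
experiment
experimental
experiments
express
expressed
expression
extract
extracted
extraction
facilities
facility
faculty
family
fellowship
few
field
figure
figures
final
financial
find
findings
first
flow
fluorescence
following
for
form
former
foundation
from
fruitful
full
fund
funded
funding
funds
further
gave
general
generous
generously
gene
genes
genetic
get
gift
gifts
give
given
gives
giving
goat
good
grant
granted
grants
grateful
gratefully
gratitude
great
greatly
group
groups
guidance
had
hand
handling
has
have
having
he
health
held
help
helped
helpful
helping
her
here
herein
high
him
his
hospital
host
how
however
human
hybridoma
hybridomas
idea
ideas
if
image
images
imaging
immune
important
in
include
included
includes
including
indebted
information
initial
input
insight
insightful
insights
institute
institution
institutional
instrument
instruments
interest
interesting
international
into
invaluable
is
it
its
itself
jr
just
keep
key
kind
kindly
know
knowledge
lab
laboratories
laboratory
large
last
late
later
lead
level
library
like
line
lines
liver
long
made
maintenance
major
make
making
managed
management
manuscript
manuscripts
many
material
materials
may
me
medal
medical
medicine
member
members
mice
microscope
microscopy
might
ministry
model
models
molecular
monoclonal
more
most
mouse
mr
mrs
ms
much
muscle
must
my
national
nature
necessary
need
needed
network
new
no
none
nor
not
now
number
numerous
of
office
on
one
ongoing
only
open
or
original
other
others
our
out
over
own
paper
part
partial
partially
particular
particularly
past
patient
patients
people
performed
permission
personal
personnel
plasma
polyclonal
possible
postdoctoral
preparation
prepared
present
presented
previous
primary
principal
prior
private
prize
process
prof
professor
program
programme
project
projects
protein
proteins
protocol
protocols
provide
provided
provides
providing
public
purified
quality
rabbit
rabbits
rat
rats
read
reader
reading
reagent
reagents
receive
received
recombinant
regional
report
research
researcher
researchers
resource
resources
respect
result
results
review
reviewer
reviewers
reviews
sample
samples
school
science
sciences
scientific
scientist
scientists
secondary
secretarial
section
sections
see
sequence
sequences
sera
serum
service
services
set
several
share
shared
sharing
she
should
sincere
sincerely
so
society
some
special
specific
sr
st
staff
state
statistical
stimulating
stock
stocks
strain
strains
student
students
studies
study
such
suggestion
suggestions
supervision
supplied
supply
supplying
support
supported
supporting
take
team
technical
technician
technicians
technique
techniques
technology
text
thank
thanked
thankful
thanks
that
the
their
them
then
there
these
they
this
those
though
through
throughout
time
tissue
tissues
to
together
too
training
trust
two
under
university
up
us
use
used
useful
uses
using
valuable
van
various
version
very
via
virus
viruses
von
was
we
well
were
what
when
where
which
while
who
whole
whom
whose
wild
will
wish
with
within
without
work
works
would
write
writing
written
year
years
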